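# Default VP1 surface-loop definitions on CsfrRNAV VP1 author numbering
# (625-894). The loop boundaries are only marked graphically in published
# figures; these spans are editable placeholders bracketing the annotated
# CD, E1E2 and EF loops between their flanking beta-strands.
name	spec
CD-Loop	700-720
E1E2-Loop	758-792
EF-Loop	800-838
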