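#' Run configuration for the full structure-phylogeny pipeline
#'
#' Assembles and validates the inputs of
#' [run_structure_phylogeny_pipeline()]. Configurations can also be stored
#' as YAML (see [read_run_config()]).
#'
#' @param structures data.frame with columns `path`, `label`, optional
#'   `trim` (N-terminal boundary; NA = no trimming) and `predicted`
#'   (logical).
#' @param out_dir output directory.
#' @param reference label of the profile reference structure (default: the
#'   first).
#' @param sequences optional FASTA path of the amino-acid sequences; when
#'   absent, sequences are taken from the structures' residues.
#' @param regions optional data.frame (`name`, `spec`) or TSV path of
#'   named regions on the reference numbering.
#' @param hosts optional host map (named vector, data.frame or TSV path).
#' @param params an [align_params()].
#' @param bootstrap_reps bootstrap replicates for the sequence tree.
#' @param seed integer seed (bootstrap resampling).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(structures, out_dir, reference = NULL,
                       sequences = NULL, regions = NULL, hosts = NULL,
                       params = align_params(), bootstrap_reps = 1000L,
                       seed = 1L) {
  stopifnot(is.data.frame(structures),
            all(c("path", "label") %in% names(structures)))
  if (anyDuplicated(structures$label)) stop_cp("duplicate structure labels")
  missing <- structures$path[!file.exists(structures$path)]
  if (length(missing))
    stop_cp("missing structure files: %s", paste(missing, collapse = ", "))
  if (is.null(structures$trim)) structures$trim <- NA_integer_
  if (is.null(structures$predicted)) structures$predicted <- FALSE
  if (is.character(regions) && length(regions) == 1)
    regions <- read.table(regions, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.character(hosts) && length(hosts) == 1) hosts <- read_host_map(hosts)
  reference <- reference %||% structures$label[1]
  if (!reference %in% structures$label)
    stop_cp("reference '%s' is not among the structure labels", reference)
  structure(list(structures = structures, out_dir = out_dir,
                 reference = reference, sequences = sequences,
                 regions = regions, hosts = hosts, params = params,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys mirror the [run_config()] arguments; `structures` is a
#' list of maps with `path`, `label`, optional `trim`/`predicted`; `params`
#' a map of [align_params()] fields.
#'
#' @param path YAML file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- do.call(rbind, lapply(y$structures, function(s)
    data.frame(path = s$path, label = s$label,
               trim = s$trim %||% NA_integer_,
               predicted = isTRUE(s$predicted))))
  pr <- do.call(align_params, y$params %||% list())
  run_config(st, out_dir = y$out_dir, reference = y$reference,
             sequences = y$sequences, regions = y$regions, hosts = y$hosts,
             params = pr, bootstrap_reps = y$bootstrap_reps %||% 1000L,
             seed = y$seed %||% 1L)
}

#' Run the full structure-phylogeny pipeline
#'
#' End-to-end workflow: read and optionally trim the structures; compute
#' the all-vs-all core-RMSD matrix and its neighbor-joining structure
#' tree; align the sequences, compute p-distances, and build the NJ
#' sequence tree with bootstrap supports; profile every structure against
#' the designated reference and average; compare the two trees
#' (Robinson-Foulds) and report host monophyly when a host map is given.
#' All artifacts, a plain-text log and a JSON run manifest are written to
#' the output directory; outputs are byte-identical for a fixed
#' configuration and seed. Any stage failure aborts with the stage name
#' and leaves a `FAILED` marker beside the partial outputs.
#'
#' @param config a [run_config()].
#' @return list with the distance matrix, both trees, the averaged
#'   profile, the RF distance and (optionally) the host report; written
#'   file paths in `$files`.
#' @export
run_structure_phylogeny_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  loglines <- character(0)
  say <- function(...) loglines <<- c(loglines, sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(loglines, sprintf("FAILED at stage '%s': %s", stage,
                                   conditionMessage(e))), logf)
    file.create(file.path(config$out_dir, "FAILED"))
    stop_cp("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  tryCatch({
    say("capsidphylo pipeline; package %s",
        as.character(utils::packageVersion("capsidphylo")))
    say("seed %d; bootstrap_reps %d; d0 %.3g; gap_open %.3g; gap_extend %.3g; core_cutoff %.3g",
        config$seed, config$bootstrap_reps, config$params$d0,
        config$params$gap_open, config$params$gap_extend,
        config$params$core_cutoff)

    stage <- "read_structures"
    if (nrow(config$structures) < 3)
      stop_cp("phylogeny needs >= 3 structures (got %d)",
              nrow(config$structures))
    structs <- lapply(seq_len(nrow(config$structures)), function(i) {
      r <- config$structures[i, ]
      read_ca_structure(r$path, predicted = isTRUE(r$predicted),
                        label = r$label)
    })
    say("read %d structures", length(structs))
    trims <- setNames(as.list(config$structures$trim),
                      config$structures$label)

    stage <- "all_vs_all_matrix"
    dmat <- all_vs_all_matrix(structs, config$params, trims)
    phylip_path <- file.path(config$out_dir, "structure_dist.phylip")
    write_phylip_dist(dmat, phylip_path)
    say("all-vs-all matrix: %d x %d, max %.3f A", nrow(dmat), ncol(dmat),
        max(dmat))

    stage <- "structure_tree"
    struct_tree <- nj_build(dmat)
    st_path <- file.path(config$out_dir, "structure_tree.nwk")
    write_newick(struct_tree, st_path)

    stage <- "sequence_tree"
    seqs <- if (!is.null(config$sequences)) {
      fasta_as_vector(read_fasta(config$sequences))
    } else {
      setNames(vapply(structs, ca_sequence, ""),
               vapply(structs, function(s) s$label, ""))
    }
    aln <- progressive_msa(seqs)
    seq_tree <- bootstrap_support(aln, n_reps = config$bootstrap_reps,
                                  seed = config$seed)
    qt_path <- file.path(config$out_dir, "sequence_tree.nwk")
    write_newick(seq_tree, qt_path)
    say("sequence tree: %d bootstrap replicates (%d skipped)",
        config$bootstrap_reps, attr(seq_tree, "n_skipped"))

    stage <- "profiles"
    trimmed <- lapply(structs, function(s) {
      bnd <- trims[[s$label]]
      if (is.null(bnd) || is.na(bnd)) s else trim_nterm_arm(s, bnd)
    })
    ref_idx <- which(config$structures$label == config$reference)
    ref <- trimmed[[ref_idx]]
    profiles <- list()
    for (i in seq_along(trimmed)) {
      if (i == ref_idx) next
      al <- pair_align(ref, trimmed[[i]], config$params)
      profiles <- c(profiles, list(
        per_residue_deviation(ref, trimmed[[i]], al$correspondence,
                              al$superposition)))
    }
    avg <- average_profiles(profiles)
    prof_path <- file.path(config$out_dir, "profile.tsv")
    write_profile_tsv(profiles, prof_path)
    region_report <- NULL
    if (!is.null(config$regions)) {
      region_report <- region_summary(avg, config$regions)
      write.table(region_report, file.path(config$out_dir, "regions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "tree_comparison"
    rf <- rf_distance(struct_tree, seq_tree)
    say("RF(structure tree, sequence tree) = %d", rf)
    host_report <- NULL
    if (!is.null(config$hosts)) {
      host_report <- rbind(
        cbind(tree = "structure", host_monophyly(struct_tree, config$hosts)),
        cbind(tree = "sequence", host_monophyly(seq_tree, config$hosts)))
      write.table(host_report, file.path(config$out_dir, "hosts_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    summary_df <- data.frame(rf_structure_vs_sequence = rf,
                             n_structures = length(structs),
                             max_rmsd = max(dmat))
    write.table(summary_df, file.path(config$out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("capsidphylo")),
      seed = config$seed, bootstrap_reps = config$bootstrap_reps,
      params = unclass(config$params),
      reference = config$reference,
      labels = config$structures$label,
      rf_structure_vs_sequence = rf)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(loglines, logf)

    list(distance_matrix = dmat, structure_tree = struct_tree,
         sequence_tree = seq_tree, profile = avg,
         region_report = region_report, rf = rf, host_report = host_report,
         files = list.files(config$out_dir, full.names = TRUE))
  }, error = on_fail)
}
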