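#' Parameters for synthetic homolog-family simulation
#'
#' Defaults describe a family the size of the curated capsid-protein set
#' the pipeline is aimed at: 12 taxa, 250-residue chains, coordinate
#' divergence 0.4 Angstrom per unit branch length and 0.3
#' substitutions/site per unit branch length, no terminal indels.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param chain_length residues per chain (>= 30).
#' @param coord_sigma Angstrom of Brownian coordinate noise per sqrt unit
#'   branch length (>= 0).
#' @param sub_rate substitutions/site per unit branch length (>= 0).
#' @param terminal_indel_max maximum N-terminal deletion length per leaf
#'   (0 disables indels).
#' @param seed integer RNG seed.
#' @return list of class `SimParams`.
#' @export
sim_params <- function(n_taxa = 12L, chain_length = 250L, coord_sigma = 0.4,
                       sub_rate = 0.3, terminal_indel_max = 0L, seed = 1L) {
  if (n_taxa < 4) stop_cp("n_taxa must be >= 4")
  if (chain_length < 30) stop_cp("chain_length must be >= 30")
  if (coord_sigma < 0) stop_cp("coord_sigma must be >= 0")
  if (sub_rate < 0) stop_cp("sub_rate must be >= 0")
  structure(list(n_taxa = as.integer(n_taxa),
                 chain_length = as.integer(chain_length),
                 coord_sigma = coord_sigma, sub_rate = sub_rate,
                 terminal_indel_max = as.integer(terminal_indel_max),
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' Idealized helical C-alpha trace
#'
#' A smooth alpha-helix-like base fold: rise 1.5 Angstrom/residue, radius
#' 2.3 Angstrom, 100 degrees/residue. Serves as the common ancestor
#' conformation for structure evolution.
#'
#' @param n residues.
#' @param label structure label.
#' @return a [ca_structure()].
#' @export
helix_fold <- function(n, label = "base") {
  i <- seq_len(n)
  theta <- (i - 1) * 100 * pi / 180
  ca_structure(label, seq_id = i,
               xyz = cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i))
}

#' Sample a random unrooted binary tree
#'
#' Random topology by sequential leaf addition (each new leaf splits a
#' uniformly chosen edge); branch lengths i.i.d. exponential with mean 0.1.
#' Reproducible per seed.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer RNG seed.
#' @param mean_branch mean branch length.
#' @param labels optional leaf labels (default `t01`, `t02`, ...).
#' @return a `phylo` with `2 n_taxa - 3` edges (unrooted, trifurcating
#'   base).
#' @export
sample_tree <- function(n_taxa, seed = 1L, mean_branch = 0.1, labels = NULL) {
  if (n_taxa < 4) stop_cp("n_taxa must be >= 4")
  set.seed(as.integer(seed))
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa, !anyDuplicated(labels))
  root <- n_taxa + 1L
  edges <- rbind(c(root, 1L), c(root, 2L), c(root, 3L))
  next_id <- root + 1L
  for (tip in seq(4L, n_taxa)) {
    e <- sample.int(nrow(edges), 1)
    v <- next_id; next_id <- next_id + 1L
    p <- edges[e, 1]; ch <- edges[e, 2]
    edges <- rbind(edges[-e, , drop = FALSE], c(p, v), c(v, ch), c(v, tip))
  }
  lens <- rexp(nrow(edges), rate = 1 / mean_branch)
  .edges_to_phylo(cbind(edges, lens), labels, root_id = root)
}

.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# accumulate per-node quantities down the tree; f(parent_value, edge_length)
.tree_accumulate <- function(tr, init, f) {
  ntip <- length(tr$tip.label)
  vals <- vector("list", ntip + tr$Nnode)
  vals[[ntip + 1L]] <- init
  for (e in seq_len(nrow(tr$edge))) {   # cladewise: parents first
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    vals[[ch]] <- f(vals[[p]], tr$edge.length[e])
  }
  vals
}

#' Evolve structures along a tree by Brownian coordinate noise
#'
#' Each tree edge of length t adds i.i.d. Gaussian displacement
#' `N(0, coord_sigma^2 * t * w_i)` per coordinate to every residue i,
#' where `w_i = loop_factor` inside the designated loop segments and 1
#' elsewhere — concentrating divergence in "loops", as observed for capsid
#' surface loops. Each leaf then receives a random rigid transform (unless
#' `rigid = FALSE`), so downstream superposition is genuinely exercised.
#'
#' @param tree a `phylo` (leaves become structure labels).
#' @param base_fold ancestor `CaStructure` (default [helix_fold()]).
#' @param coord_sigma Angstrom per sqrt unit branch length (>= 0).
#' @param seed integer RNG seed.
#' @param loop_segments `SegmentSet` of accelerated segments (default: a
#'   single segment spanning 40-52% of the chain).
#' @param loop_factor variance multiplier inside loops (default 4).
#' @param rigid apply a random rigid transform per leaf (default TRUE).
#' @return named list of `CaStructure`s (one per leaf, tree tip order).
#' @export
evolve_structures <- function(tree, base_fold = NULL, coord_sigma = 0.4,
                              seed = 1L, loop_segments = NULL,
                              loop_factor = 4, rigid = TRUE) {
  if (coord_sigma < 0) stop_cp("coord_sigma must be >= 0")
  ntip <- length(tree$tip.label)
  if (is.null(base_fold)) base_fold <- helix_fold(250L)
  n <- length(base_fold)
  if (is.null(loop_segments))
    loop_segments <- segment_set(round(0.40 * n), round(0.52 * n))
  w <- ifelse(in_segments(loop_segments, base_fold$residues$seq_id),
              loop_factor, 1)
  set.seed(as.integer(seed))
  disp <- .tree_accumulate(tree, matrix(0, n, 3), function(parent, t) {
    parent + matrix(rnorm(3 * n, sd = coord_sigma * sqrt(t * w)), n, 3)
  })
  base_xyz <- ca_coords(base_fold)
  out <- lapply(seq_len(ntip), function(i) {
    xyz <- base_xyz + disp[[i]]
    if (rigid) {
      R <- .random_rotation()
      xyz <- xyz %*% t(R) + matrix(runif(3, -30, 30), n, 3, byrow = TRUE)
    }
    ca_structure(tree$tip.label[i], base_fold$residues$seq_id, xyz,
                 aa = base_fold$residues$aa)
  })
  names(out) <- tree$tip.label
  attr(out, "loop_segments") <- loop_segments
  out
}

#' Evolve sequences along a tree by a Poisson substitution process
#'
#' Per edge of length t each site substitutes with probability
#' `1 - exp(-sub_rate * t)`; the replacement residue is uniform over the
#' other 19 amino acids.
#'
#' @param tree a `phylo`.
#' @param root_seq ancestor sequence (character scalar); default random.
#' @param sub_rate substitutions/site per unit branch length.
#' @param seed integer RNG seed.
#' @return named character vector of leaf sequences (tree tip order).
#' @export
evolve_sequences <- function(tree, root_seq = NULL, sub_rate = 0.3,
                             seed = 1L) {
  if (sub_rate < 0) stop_cp("sub_rate must be >= 0")
  aa20 <- .blosum62_order
  set.seed(as.integer(seed))
  if (is.null(root_seq)) root_seq <- paste(sample(aa20, 250, TRUE), collapse = "")
  root <- strsplit(toupper(root_seq), "")[[1]]
  L <- length(root)
  seqs <- .tree_accumulate(tree, root, function(parent, t) {
    hit <- runif(L) < 1 - exp(-sub_rate * t)
    if (any(hit)) {
      parent[hit] <- vapply(parent[hit],
                            function(a) sample(setdiff(aa20, a), 1), "")
    }
    parent
  })
  ntip <- length(tree$tip.label)
  setNames(vapply(seqs[seq_len(ntip)], paste, "", collapse = ""),
           tree$tip.label)
}

# host assignment: the clades hanging off the tree's basal node
.hosts_from_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sets <- .edge_tipsets(tree)
  hosts <- setNames(rep(NA_character_, ntip), tree$tip.label)
  for (k in seq_along(kids)) {
    e <- which(tree$edge[, 1] == root & tree$edge[, 2] == kids[k])
    hosts[sets[[e]]] <- sprintf("host%d", k)
  }
  hosts
}

#' Simulate a complete homolog family
#'
#' Samples a random true tree, evolves co-diverging coordinates and
#' sequences along it, optionally applies N-terminal deletions per leaf
#' (shared between sequence and structure), and derives host labels from
#' the clades at the tree's basal node — giving every downstream stage a
#' ground truth to recover.
#'
#' @param params a [sim_params()].
#' @return list of class `SimFamily`: `true_tree`, `structures`,
#'   `sequences`, `hosts`, `params`.
#' @export
sim_family <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimParams"))
  tree <- sample_tree(params$n_taxa, seed = params$seed)
  base <- helix_fold(params$chain_length)
  # root sequence length must match the chain
  set.seed(params$seed + 1L)
  root_seq <- paste(sample(.blosum62_order, params$chain_length, TRUE),
                    collapse = "")
  seqs <- evolve_sequences(tree, root_seq = root_seq,
                           sub_rate = params$sub_rate,
                           seed = params$seed + 2L)
  structs <- evolve_structures(tree, base_fold = base,
                               coord_sigma = params$coord_sigma,
                               seed = params$seed + 3L)
  # stamp each structure's residues with its evolved sequence
  structs <- lapply(structs, function(s) {
    aa <- strsplit(seqs[[s$label]], "")[[1]]
    ca_structure(s$label, s$residues$seq_id,
                 as.matrix(s$residues[, c("x", "y", "z")]), aa = aa)
  })
  names(structs) <- tree$tip.label
  if (params$terminal_indel_max > 0) {
    set.seed(params$seed + 4L)
    dels <- sample.int(params$terminal_indel_max + 1L, params$n_taxa,
                       replace = TRUE) - 1L
    for (i in seq_along(structs)) {
      k <- dels[i]
      if (k > 0) {
        structs[[i]] <- trim_nterm_arm(structs[[i]], k + 1L)
        lab <- names(structs)[i]
        seqs[[lab]] <- substring(seqs[[lab]], k + 1L)
      }
    }
  }
  structure(list(true_tree = tree, structures = structs, sequences = seqs,
                 hosts = .hosts_from_tree(tree), params = params),
            class = "SimFamily")
}

#' @export
print.SimFamily <- function(x, ...) {
  cat(sprintf("SimFamily: %d taxa, chain %d, coord_sigma %.2f, sub_rate %.2f\n",
              x$params$n_taxa, x$params$chain_length, x$params$coord_sigma,
              x$params$sub_rate))
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits one PDB-format CA trace per structure, one FASTA of all
#' sequences, the true tree as Newick, and the host map as TSV.
#'
#' @param params a [sim_params()] (or an already-built `SimFamily`).
#' @param outdir output directory (created if needed).
#' @return the in-memory `SimFamily`, invisibly; attribute `files` lists
#'   the written paths.
#' @export
emit_family <- function(params, outdir) {
  fam <- if (inherits(params, "SimFamily")) params else sim_family(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in fam$structures) {
    p <- file.path(outdir, paste0(s$label, ".pdb"))
    write_ca_structure(s, p)
    files <- c(files, p)
  }
  fa <- file.path(outdir, "sequences.fasta")
  write_fasta(fam$sequences, fa)
  nw <- file.path(outdir, "true_tree.nwk")
  write_newick(fam$true_tree, nw)
  hm <- file.path(outdir, "hosts.tsv")
  write_host_map(fam$hosts, hm)
  attr(fam, "files") <- c(files, fa, nw, hm)
  invisible(fam)
}
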