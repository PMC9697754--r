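#' Per-residue deviation profile on a reference structure
#'
#' For each residue of the reference `a` matched in the correspondence, the
#' Euclidean CA-CA deviation (Angstrom) to its partner in `b` after applying
#' the single global superposition `sup`. Unmatched reference residues are
#' missing (NA). No per-window refitting is performed: all deviations are
#' measured in one frame, the behavior of per-residue RMSD coloring tools.
#'
#' @param a reference `CaStructure`; profile keys are its `seq_id`s.
#' @param b compared `CaStructure`.
#' @param corr [correspondence()] between a and b.
#' @param sup `Superposition` derived from `corr` (e.g. from [pair_align()]).
#' @return object of class `RmsdProfile`: list with `reference` (label),
#'   `values` (named numeric over all reference seq_ids; NA = unmatched),
#'   `window` (1).
#' @export
per_residue_deviation <- function(a, b, corr, sup) {
  stopifnot(inherits(a, "CaStructure"), inherits(b, "CaStructure"),
            inherits(corr, "Correspondence"), inherits(sup, "Superposition"))
  if (nrow(corr) == 0) stop_cp("empty correspondence")
  dev <- sqrt(rowSums((ca_coords(a)[corr$ai, , drop = FALSE] -
                       apply_superposition(sup, ca_coords(b)[corr$bi, , drop = FALSE]))^2))
  vals <- rep(NA_real_, length(a))
  vals[corr$ai] <- dev
  names(vals) <- a$residues$seq_id
  structure(list(reference = a$label, values = vals, window = 1L),
            class = "RmsdProfile")
}

#' Construct an RmsdProfile from raw values
#' @param reference reference label.
#' @param values named numeric vector (names = reference seq_ids; NA allowed).
#' @param window window width used to produce the values.
#' @return `RmsdProfile`.
#' @export
rmsd_profile <- function(reference, values, window = 1L) {
  if (any(values < 0, na.rm = TRUE)) stop_cp("profile values must be >= 0")
  if (is.null(names(values))) stop_cp("profile values must be named by seq_id")
  structure(list(reference = reference, values = values,
                 window = as.integer(window)),
            class = "RmsdProfile")
}

#' @export
print.RmsdProfile <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("RmsdProfile on '%s': %d/%d residues, window %d, max %.2f A\n",
              x$reference, length(v), length(x$values), x$window,
              if (length(v)) max(v) else NA))
  invisible(x)
}

#' Windowed root-mean-square smoothing of a profile
#'
#' The value at residue i becomes the root mean square of the per-residue
#' deviations over matched residues within +/- (w-1)/2 sequence positions of
#' i (by profile order). Residues with no matched neighbor in the window are
#' missing. `w = 1` returns the input unchanged.
#'
#' @param p an `RmsdProfile` with window 1.
#' @param w odd window width >= 1.
#' @return smoothed `RmsdProfile`.
#' @export
windowed_profile <- function(p, w) {
  stopifnot(inherits(p, "RmsdProfile"))
  w <- as.integer(w)
  if (w < 1 || w %% 2L == 0L) stop_cp("window width must be odd and >= 1")
  if (w == 1L) return(p)
  half <- (w - 1L) %/% 2L
  v <- p$values
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - half):min(n, i + half)
    vv <- v[idx]
    vv <- vv[!is.na(vv)]
    if (length(vv)) out[i] <- sqrt(mean(vv^2))
  }
  names(out) <- names(v)
  rmsd_profile(p$reference, out, window = w)
}

#' Average multiple profiles on a shared reference
#'
#' Per-residue arithmetic mean over the profiles in which the residue is
#' present; a residue is missing only if missing in every profile. This is
#' the "averaged RMSD per residue map" used to color a reference structure
#' by the mean divergence of a whole family.
#'
#' @param profiles list of `RmsdProfile`s on the same reference.
#' @return averaged `RmsdProfile`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 1) stop_cp("need at least one profile")
  refs <- unique(vapply(profiles, function(p) p$reference, ""))
  if (length(refs) != 1)
    stop_cp("profiles are on mixed references: %s", paste(refs, collapse = ", "))
  keys <- names(profiles[[1]]$values)
  for (p in profiles) {
    if (!identical(names(p$values), keys))
      stop_cp("profiles cover different residue sets")
  }
  m <- do.call(rbind, lapply(profiles, function(p) p$values))
  means <- colMeans(m, na.rm = TRUE)
  means[colSums(!is.na(m)) == 0] <- NA_real_
  rmsd_profile(refs, means, window = profiles[[1]]$window)
}

#' Named-region summaries of a profile
#'
#' Per-region statistics (mean, max, count of present values) over regions
#' given in reference numbering — e.g. the CD, E1E2 and EF surface loops of
#' a capsid VP1. Regions with no present value get `n = 0` and NA
#' statistics.
#'
#' @param p an `RmsdProfile`.
#' @param regions named list of `SegmentSet`s (names = region names), or a
#'   data.frame with columns `name`, `spec` (range strings).
#' @return data.frame with columns `region`, `mean`, `max`, `n`.
#' @export
region_summary <- function(p, regions) {
  stopifnot(inherits(p, "RmsdProfile"))
  if (is.data.frame(regions)) {
    regions <- setNames(lapply(regions$spec, parse_segment_spec), regions$name)
  }
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop_cp("regions must be named")
  seq_ids <- as.integer(names(p$values))
  rows <- lapply(names(regions), function(nm) {
    s <- regions[[nm]]
    if (nrow(s) == 0) stop_cp("region '%s' has no segments", nm)
    vv <- p$values[in_segments(s, seq_ids)]
    vv <- vv[!is.na(vv)]
    data.frame(region = nm,
               mean = if (length(vv)) mean(vv) else NA_real_,
               max = if (length(vv)) max(vv) else NA_real_,
               n = length(vv))
  })
  do.call(rbind, rows)
}

#' Write a profile (or several) as TSV
#'
#' Columns: `seq_id`, one deviation column per profile, and `mean` when
#' more than one profile is given. Suitable for re-plotting or for
#' structure-viewer attribute coloring.
#'
#' @param profiles a single `RmsdProfile` or list of them (shared reference).
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "RmsdProfile")) profiles <- list(profiles)
  avg <- if (length(profiles) > 1) average_profiles(profiles) else NULL
  df <- data.frame(seq_id = as.integer(names(profiles[[1]]$values)))
  for (i in seq_along(profiles)) df[[paste0("dev_", i)]] <- unname(profiles[[i]]$values)
  if (!is.null(avg)) df$mean <- unname(avg$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
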