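#' State-assignment configuration
#'
#' Mini inteins are distinguished from large inteins within an allele by a gap
#' of at least `gap_cutoff` (default 100 aa) in the sorted intein lengths. For
#' alleles without such a gap, all members receive one state, decided by
#' whether the median length reaches `fallback_floor` (default 300 aa, below
#' typical two-domain inteins and above splicing-only domains).
#'
#' @param gap_cutoff minimum within-allele length gap (aa) separating mini
#'   from large.
#' @param fallback_floor single-state decision boundary (aa) for gap-free
#'   alleles.
#' @param hen_overlap_min minimum fraction of a mini's alignment gap columns
#'   that must fall inside the HEN region for [verify_hen_gap()].
#' @return A `state_config` list.
#' @export
state_config <- function(gap_cutoff = 100L, fallback_floor = 300L,
                         hen_overlap_min = 0.8) {
  if (gap_cutoff <= 0) stopf("gap_cutoff must be > 0")
  if (fallback_floor <= 0) stopf("fallback_floor must be > 0")
  if (hen_overlap_min < 0 || hen_overlap_min > 1)
    stopf("hen_overlap_min must be in [0, 1]")
  structure(list(gap_cutoff = as.numeric(gap_cutoff),
                 fallback_floor = as.numeric(fallback_floor),
                 hen_overlap_min = hen_overlap_min),
            class = "state_config")
}

#' Assign mini/large states within one allele by the length-gap rule
#'
#' The unique intein lengths of the allele are sorted and the largest adjacent
#' gap located. If that gap is at least `gap_cutoff`, lengths below the gap
#' midpoint are MINI and lengths above it LARGE (ties among equally large gaps
#' are broken toward the gap at smaller lengths, which is conservative toward
#' the canonical large state). If no gap reaches the cutoff, all members
#' receive a single state: LARGE when the median length is at least
#' `fallback_floor`, otherwise MINI. The result is invariant to input order
#' and to duplicated lengths.
#'
#' @param lengths named numeric vector of intein lengths (aa) per genome for
#'   one allele; all positive.
#' @param config a [state_config()].
#' @return Named character vector over `"MINI"`/`"LARGE"`, with attributes
#'   `threshold` (the midpoint cut, or `NA` for the fallback) and
#'   `low_confidence` (`TRUE` when only one sequence was available).
#' @export
#' @examples
#' assign_states(c(a = 150, b = 160, c = 480, d = 500))
assign_states <- function(lengths, config = state_config()) {
  if (length(lengths) < 1) stopf("need at least one length")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("lengths must be positive and finite")
  u <- sort(unique(as.numeric(lengths)))
  threshold <- NA_real_
  if (length(u) >= 2) {
    gaps <- diff(u)
    gmax <- max(gaps)
    if (gmax >= config$gap_cutoff) {
      i <- which(gaps == gmax)[1]          # tie -> gap at smaller length
      threshold <- (u[i] + u[i + 1]) / 2
    }
  }
  states <- if (!is.na(threshold)) {
    ifelse(lengths < threshold, "MINI", "LARGE")
  } else {
    rep(if (median(lengths) >= config$fallback_floor) "LARGE" else "MINI",
        length(lengths))
  }
  states <- setNames(as.character(states), names(lengths))
  attr(states, "threshold") <- threshold
  attr(states, "low_confidence") <- length(lengths) == 1
  states
}

#' Verify that mini-intein alignment gaps coincide with the HEN region
#'
#' For each putative mini intein, computes the fraction of its gap columns in
#' the allele alignment that fall inside the HEN region, and calls the mini
#' verified when that fraction reaches `hen_overlap_min`. If no HEN region is
#' supplied it is estimated as the maximal column interval where at least 80%
#' of large rows are residues and at least 80% of mini rows are gaps.
#'
#' @param alignment allele alignment (named; any form accepted by
#'   [build_pssm()]) containing mini and large rows.
#' @param mini_ids row names of the putative minis.
#' @param hen_region optional integer vector `c(from, to)` of 1-based
#'   alignment columns.
#' @param large_ids row names of the large inteins (default: all non-mini
#'   rows).
#' @param config a [state_config()].
#' @return Named logical vector over `mini_ids`, with the used region in
#'   attribute `hen_region`.
#' @export
verify_hen_gap <- function(alignment, mini_ids, hen_region = NULL,
                           large_ids = NULL, config = state_config()) {
  m <- as_alignment_matrix(alignment)
  if (is.null(rownames(m))) stopf("alignment rows must be named")
  unknown <- setdiff(mini_ids, rownames(m))
  if (length(unknown))
    stopf("unknown mini id(s): %s", paste(unknown, collapse = ", "))
  if (is.null(large_ids)) large_ids <- setdiff(rownames(m), mini_ids)
  if (is.null(hen_region)) {
    if (!length(large_ids)) stopf("cannot estimate HEN region without large rows")
    gm <- colMeans(m[mini_ids, , drop = FALSE] == "-") >= 0.8
    lr <- colMeans(m[large_ids, , drop = FALSE] != "-") >= 0.8
    good <- gm & lr
    if (!any(good)) stopf("no candidate HEN interval found in the alignment")
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$values)[which.max(r$lengths[r$values])]
    hen_region <- c(starts[i], ends[i])
  }
  if (hen_region[1] < 1 || hen_region[2] > ncol(m) ||
      hen_region[1] > hen_region[2])
    stopf("hen_region out of alignment bounds")
  res <- vapply(mini_ids, function(id) {
    gaps <- which(m[id, ] == "-")
    if (!length(gaps)) return(FALSE)
    mean(gaps >= hen_region[1] & gaps <= hen_region[2]) >= config$hen_overlap_min
  }, TRUE)
  attr(res, "hen_region") <- hen_region
  res
}

#' Genome-by-allele state profile
#'
#' Container for the presence-absence-state matrix over
#' `{ABSENT, MINI, LARGE, MISSING}` with optional per-cell intein lengths.
#' MINI/LARGE cells must carry a length when a length matrix is supplied;
#' ABSENT/MISSING cells must not.
#'
#' @param states character matrix (genomes x alleles) with dimnames, cells in
#'   `ABSENT`, `MINI`, `LARGE`, `MISSING`.
#' @param lengths optional numeric matrix of the same shape.
#' @return An object of class `allele_profile` with elements `states`,
#'   `lengths`, `genomes`, `alleles`.
#' @export
allele_profile <- function(states, lengths = NULL) {
  if (!is.matrix(states) || is.null(rownames(states)) || is.null(colnames(states)))
    stopf("states must be a matrix with genome row names and allele column names")
  if (anyDuplicated(rownames(states)) || anyDuplicated(colnames(states)))
    stopf("genome and allele ids must be unique")
  bad <- setdiff(unique(c(states)), c("ABSENT", "MINI", "LARGE", "MISSING"))
  if (length(bad))
    stopf("invalid state value(s): %s", paste(bad, collapse = ", "))
  if (!is.null(lengths)) {
    stopifnot(identical(dim(lengths), dim(states)))
    dimnames(lengths) <- dimnames(states)
    present <- states %in% c("MINI", "LARGE")
    if (any(present & is.na(lengths)))
      stopf("every MINI/LARGE cell must have a length")
    if (any(!present & !is.na(lengths)))
      stopf("ABSENT/MISSING cells must not carry a length")
  }
  structure(list(states = states, lengths = lengths,
                 genomes = rownames(states), alleles = colnames(states)),
            class = "allele_profile")
}

#' @export
print.allele_profile <- function(x, ...) {
  cat(sprintf("allele_profile: %d genomes x %d alleles\n",
              length(x$genomes), length(x$alleles)))
  tab <- table(factor(x$states, levels = c("ABSENT", "MINI", "LARGE", "MISSING")))
  cat("  ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Merge detection hits and state assignments into an allele profile
#'
#' Each genome x allele cell becomes: the assigned MINI/LARGE state where a
#' hit exists; ABSENT where the orthologous host gene is present without an
#' insertion; MISSING where the host gene was not found. Hits whose insertion
#' abuts a sequence end (`truncated`) are demoted to MISSING, since truncated
#' sequences cannot be assigned a symbiotic state from length.
#'
#' @param hits data frame with at least `genome`, `allele`, `length` (as from
#'   [detect_allele()]); an optional logical `truncated` column triggers the
#'   demotion rule.
#' @param assignments named list per allele of named state vectors from
#'   [assign_states()].
#' @param genomes the full genome universe (character vector).
#' @param ortholog_presence logical matrix (genomes x alleles): was the host
#'   gene found in that genome?
#' @return An [allele_profile()].
#' @export
merge_states <- function(hits, assignments, genomes, ortholog_presence) {
  alleles <- colnames(ortholog_presence)
  stopifnot(!is.null(alleles),
            identical(rownames(ortholog_presence), genomes))
  dup <- duplicated(hits[, c("genome", "allele")])
  if (any(dup)) {
    d <- unique(paste0(hits$genome[dup], "/", hits$allele[dup]))
    stopf("conflicting duplicate hits for cell(s): %s", paste(d, collapse = ", "))
  }
  unknown <- setdiff(unique(hits$genome), genomes)
  if (length(unknown))
    stopf("hit genome(s) outside the genome universe: %s",
          paste(unknown, collapse = ", "))
  states <- matrix("MISSING", length(genomes), length(alleles),
                   dimnames = list(genomes, alleles))
  states[ortholog_presence] <- "ABSENT"
  lens <- matrix(NA_real_, length(genomes), length(alleles),
                 dimnames = list(genomes, alleles))
  for (i in seq_len(nrow(hits))) {
    g <- hits$genome[i]; a <- hits$allele[i]
    if (!a %in% alleles) stopf("hit allele '%s' not in ortholog_presence", a)
    if (!is.null(hits$truncated) && isTRUE(hits$truncated[i])) {
      states[g, a] <- "MISSING"
      next
    }
    st <- assignments[[a]][[g]]
    if (is.null(st) || is.na(st))
      stopf("no state assignment for %s/%s", g, a)
    states[g, a] <- st
    lens[g, a] <- hits$length[i]
  }
  allele_profile(states, lens)
}
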