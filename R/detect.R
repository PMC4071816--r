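#' Detection configuration
#'
#' An intein domain adds roughly 100-700 aa to an invaded protein; insertions
#' outside that envelope are rejected as false positives. The PSSM scan
#' threshold defaults to a value calibrated on the simulator's random-protein
#' null (see the methods vignette); `min_block_len` is the minimum insertion
#' run reported by [extract_insertion()].
#'
#' @param min_added_len,max_added_len size-exclusion window in aa.
#' @param pssm_score_threshold scan threshold in bits.
#' @param min_block_len minimum reported insertion-block length in aa.
#' @return A `detection_config` list.
#' @export
detection_config <- function(min_added_len = 100L, max_added_len = 700L,
                             pssm_score_threshold = 10, min_block_len = 50L) {
  if (min_added_len <= 0 || min_added_len >= max_added_len)
    stopf("need 0 < min_added_len < max_added_len")
  if (min_block_len < 1) stopf("min_block_len must be >= 1")
  structure(list(min_added_len = as.integer(min_added_len),
                 max_added_len = as.integer(max_added_len),
                 pssm_score_threshold = pssm_score_threshold,
                 min_block_len = as.integer(min_block_len)),
            class = "detection_config")
}

# Internal: normalise an alignment argument (named character vector, character
# matrix, or AAStringSet) to an uppercase character matrix of single residues.
as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (!is.character(alignment) || length(alignment) == 0)
      stopf("alignment must be a non-empty character vector, matrix or AAStringSet")
    w <- nchar(alignment)
    if (length(unique(w)) != 1)
      stopf("aligned sequences must all have the same length (got lengths %s)",
            paste(unique(w), collapse = ", "))
    if (w[1] == 0) stopf("alignment has zero columns")
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  m[m == "."] <- "-"
  bad <- setdiff(unique(c(m)), c(AA_ALPHABET20, "-"))
  if (length(bad))
    stopf("alignment contains characters outside the amino-acid alphabet: %s",
          paste(bad, collapse = " "))
  m
}

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Per-column residue frequencies are mixed with a background distribution via
#' background-proportional pseudocounts, and scores are the log-odds
#' `log2(p / background)` in bits. Columns with more than 50% gaps are dropped
#' and recorded in the result.
#'
#' @param alignment >= 2 aligned amino-acid sequences of equal length (named
#'   character vector, character matrix, or `AAStringSet`); gaps as `-`.
#' @param pseudocount_weight non-negative pseudocount mass (default 1; values
#'   of 0 can yield `-Inf` scores for unobserved residues).
#' @param background per-residue background frequencies (named over the 20
#'   residues, summing to 1); default uniform.
#' @return An object of class `intein_pssm` with elements `scores` (20 x L
#'   matrix, bits), `background`, `pseudocount_weight`, `length`,
#'   `dropped_columns` (1-based indices of gap-majority columns in the input),
#'   `consensus` and `max_score`.
#' @export
#' @examples
#' aln <- c(s1 = "CLDHN", s2 = "CLEHN", s3 = "CMDHN")
#' p <- build_pssm(aln)
#' p$consensus
build_pssm <- function(alignment, pseudocount_weight = 1, background = NULL) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2) stopf("need at least 2 aligned sequences")
  if (pseudocount_weight < 0) stopf("pseudocount_weight must be >= 0")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET20)
  } else {
    background <- background[AA_ALPHABET20]
    if (anyNA(background) || abs(sum(background) - 1) > 1e-9)
      stopf("background must cover the 20 residues and sum to 1")
  }
  gap_frac <- colMeans(m == "-")
  dropped <- which(gap_frac > 0.5)
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stopf("all alignment columns are gap-majority")
  counts <- apply(m[, keep, drop = FALSE], 2, function(col) {
    tabulate(match(col[col != "-"], AA_ALPHABET20), nbins = 20L)
  })
  rownames(counts) <- AA_ALPHABET20
  n_eff <- colSums(counts)
  p <- sweep(counts + pseudocount_weight * background, 2,
             n_eff + pseudocount_weight, "/")
  scores <- log2(p / background)
  cons_idx <- apply(scores, 2, which.max)
  structure(list(scores = scores, background = background,
                 pseudocount_weight = pseudocount_weight,
                 length = length(keep), dropped_columns = dropped,
                 consensus = paste(AA_ALPHABET20[cons_idx], collapse = ""),
                 max_score = sum(apply(scores, 2, max))),
            class = "intein_pssm")
}

#' @export
print.intein_pssm <- function(x, ...) {
  cat(sprintf("intein_pssm: %d positions, max score %.1f bits (%d gap-majority columns dropped)\n",
              x$length, x$max_score, length(x$dropped_columns)))
  invisible(x)
}

#' Score a full-length sequence against a PSSM at a fixed offset
#'
#' @param pssm an `intein_pssm`.
#' @param seq amino-acid string of length >= `pssm$length`.
#' @param offset 0-based offset of the window.
#' @return Window score in bits.
#' @export
pssm_score <- function(pssm, seq, offset = 0L) {
  v <- aa_to_code(toupper(seq))
  L <- pssm$length
  if (offset < 0 || offset + L > length(v)) stopf("window out of bounds")
  sum(pssm$scores[cbind(v[(offset + 1L):(offset + L)], seq_len(L))])
}

#' Scan a protein for PSSM windows above a score threshold
#'
#' All windows scoring at least `threshold` bits are reported; overlapping
#' windows are merged keeping the single best-scoring window per overlap
#' cluster (ties broken toward the smaller start coordinate). A protein
#' shorter than the PSSM yields an empty result, not an error.
#'
#' @param pssm an `intein_pssm`.
#' @param protein amino-acid string.
#' @param threshold score threshold in bits.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `score`.
#' @export
scan_pssm <- function(pssm, protein, threshold) {
  empty <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  protein <- toupper(protein)
  L <- pssm$length
  n <- nchar(protein)
  if (n < L) return(empty)
  v <- aa_to_code(protein)
  S <- pssm$scores[v, , drop = FALSE]       # n x L lookup
  n_off <- n - L + 1L
  tot <- numeric(n_off)
  for (j in seq_len(L)) tot <- tot + S[j:(j + n_off - 1L), j]
  hit <- which(tot >= threshold)
  if (!length(hit)) return(empty)
  # merge overlapping windows, keeping the best score (tie -> smaller start)
  res <- list()
  cl_start <- hit[1]
  best <- hit[1]
  prev <- hit[1]
  for (h in hit[-1]) {
    if (h - 1L < prev + L) {               # overlaps the running cluster
      if (tot[h] > tot[best]) best <- h
    } else {
      res[[length(res) + 1L]] <- best
      best <- h
    }
    prev <- h
  }
  res[[length(res) + 1L]] <- best
  idx <- unlist(res)
  data.frame(start = idx - 1L, end = idx - 1L + L, score = tot[idx])
}

#' Extract insertion blocks from a host protein by ortholog comparison
#'
#' Globally aligns the host protein to an intein-free ortholog (affine gaps,
#' BLOSUM62, gap open 11 / extend 1) and reports maximal runs of host-only
#' columns of length at least `min_block_len` as candidate insertions, in
#' host coordinates (0-based half-open). Each block is anchored if up to
#' `flank` host residues on each side align to the ortholog with at least
#' `flank_min_ident` identity (conserved-site requirement); blocks at a
#' sequence terminus fail anchoring on that side.
#'
#' Insertion runs separated by at most `merge_gap` alignment columns are
#' merged into one block: a handful of coincidental residue matches inside a
#' long insertion otherwise splits it in two. Genuinely distinct insertions
#' are separated by long stretches of aligned extein and are unaffected.
#'
#' @param host host protein sequence (string).
#' @param ortholog intein-free ortholog sequence (string).
#' @param min_block_len minimum insertion length reported.
#' @param flank number of flanking host residues checked on each side.
#' @param flank_min_ident minimum flank identity in `[0, 1]`.
#' @param merge_gap maximum number of intervening alignment columns across
#'   which two insertion runs are merged.
#' @return Data frame with columns `start`, `end`, `length`, `anchored`,
#'   `seq`. Identical sequences yield an empty frame.
#' @export
#' @examples
#' orth <- strrep("ACDEFGHIKL", 30)
#' host <- paste0(substr(orth, 1, 150), strrep("W", 120), substr(orth, 151, 300))
#' extract_insertion(host, orth, min_block_len = 50)
extract_insertion <- function(host, ortholog, min_block_len = 50L,
                              flank = 10L, flank_min_ident = 0.5,
                              merge_gap = 10L) {
  if (!nzchar(host) || !nzchar(ortholog)) stopf("sequences must be non-empty")
  host <- toupper(host)
  ortholog <- toupper(ortholog)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), anchored = logical(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (identical(host, ortholog)) return(empty)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(host),
    subject = Biostrings::AAString(ortholog),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  ph <- strsplit(as.character(Biostrings::pattern(pa)), "", fixed = TRUE)[[1]]
  po <- strsplit(as.character(Biostrings::subject(pa)), "", fixed = TRUE)[[1]]
  hpos <- cumsum(ph != "-")                 # host residue index per column
  ins <- ph != "-" & po == "-"
  r <- rle(ins)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  # merge insertion runs separated by short stretches of aligned columns
  merged <- list(c(starts[runs[1]], ends[runs[1]]))
  for (i in runs[-1]) {
    last <- merged[[length(merged)]]
    if (starts[i] - last[2] - 1L <= merge_gap)
      merged[[length(merged)]] <- c(last[1], ends[i])
    else merged[[length(merged) + 1L]] <- c(starts[i], ends[i])
  }
  keep_len <- vapply(merged, function(b) hpos[b[2]] - (hpos[b[1]] - 1L), 0L)
  merged <- merged[keep_len >= min_block_len]
  if (!length(merged)) return(empty)
  out <- lapply(merged, function(b) {
    c1 <- b[1]; c2 <- b[2]
    start0 <- hpos[c1] - 1L
    end0 <- hpos[c2]
    flank_ok <- function(cols) {
      cols <- cols[cols >= 1 & cols <= length(ph)]
      cols <- cols[ph[cols] != "-"]
      if (length(cols) > flank) cols <- sort(cols)[seq_len(flank)]
      if (!length(cols)) return(FALSE)
      mean(ph[cols] == po[cols] & po[cols] != "-") >= flank_min_ident
    }
    left_ok <- if (c1 == 1L) FALSE else flank_ok(seq(c1 - flank, c1 - 1L))
    right_ok <- if (c2 == length(ph)) FALSE else flank_ok(seq(c2 + 1L, c2 + flank))
    list(start = start0, end = end0, length = end0 - start0,
         anchored = left_ok && right_ok,
         seq = substr(host, start0 + 1L, end0))
  })
  data.frame(start = vapply(out, `[[`, 0L, "start"),
             end = vapply(out, `[[`, 0L, "end"),
             length = vapply(out, `[[`, 0L, "length"),
             anchored = vapply(out, `[[`, TRUE, "anchored"),
             seq = vapply(out, `[[`, "", "seq"), stringsAsFactors = FALSE)
}

#' Size-exclusion filter for candidate insertions
#'
#' Keeps a block if and only if its length lies within the configured intein
#' size envelope (default 100-700 aa).
#'
#' @param block_length insertion length(s) in aa (vectorised).
#' @param config a [detection_config()].
#' @return Logical vector: `TRUE` = keep.
#' @export
size_filter <- function(block_length, config = detection_config()) {
  if (any(block_length < 0)) stopf("block_length must be >= 0")
  block_length >= config$min_added_len & block_length <= config$max_added_len
}

#' Check canonical intein splicing motifs
#'
#' Canonical self-splicing requires a nucleophile at the intein N-terminus
#' (Cys/Ser/Ala), an Asn or Gln at the C-terminus (typically preceded by His),
#' and a nucleophilic +1 extein residue (Cys/Ser/Thr) immediately downstream
#' of the insertion site. An unknown +1 residue leaves that check
#' indeterminate and the overall call becomes a provisional pass if both
#' termini hold.
#'
#' @param intein_seq intein amino-acid sequence (non-empty string).
#' @param plus_one_residue the first extein residue after the insertion, or
#'   `NA` if unknown.
#' @return A list with logical fields `n_terminal_ok`, `c_terminal_ok`,
#'   `plus_one_ok` (`NA` when indeterminate), `pass` and `provisional`.
#' @export
#' @examples
#' verify_splicing_motifs("CAAAAHN", "S")
verify_splicing_motifs <- function(intein_seq, plus_one_residue = NA) {
  if (!is.character(intein_seq) || length(intein_seq) != 1 || !nzchar(intein_seq))
    stopf("intein_seq must be a non-empty string")
  s <- toupper(intein_seq)
  n <- nchar(s)
  first <- substr(s, 1, 1)
  last <- substr(s, n, n)
  last2 <- if (n >= 2) substr(s, n - 1, n) else last
  n_ok <- first %in% c("C", "S", "A")
  c_ok <- last2 %in% c("HN", "HQ") || last %in% c("N", "Q")
  p1 <- if (is.na(plus_one_residue) || !nzchar(plus_one_residue)) NA_character_
        else toupper(plus_one_residue)
  p_ok <- if (is.na(p1)) NA else p1 %in% c("C", "S", "T")
  pass <- n_ok && c_ok && (is.na(p_ok) || p_ok)
  list(n_terminal_ok = n_ok, c_terminal_ok = c_ok, plus_one_ok = p_ok,
       pass = pass, provisional = n_ok && c_ok && is.na(p_ok))
}

# Internal: slide block boundaries within a small window to the registration
# that best matches the canonical splicing residues. Alignment placement of an
# insertion is ambiguous when flanking extein residues resemble the intein
# termini (common: both the intein N-terminus and the +1 extein residue are
# small nucleophiles), so the raw block can be off by a residue or two.
refine_block <- function(host, start, end, window = 3L) {
  n <- nchar(host)
  best <- c(0L, 0L)
  best_score <- -Inf
  for (di in -window:window) for (dj in -window:window) {
    s <- start + di
    e <- end + dj
    if (s < 0 || e > n || e - s < 3) next
    m <- verify_splicing_motifs(substr(host, s + 1L, e),
                                if (e < n) substr(host, e + 1L, e + 1L) else NA)
    score <- 2 * m$n_terminal_ok + 2 * m$c_terminal_ok +
      isTRUE(m$plus_one_ok) - (abs(di) + abs(dj)) / 100
    if (score > best_score) {
      best_score <- score
      best <- c(di, dj)
    }
  }
  c(start = start + best[1], end = end + best[2])
}

#' Detect intein insertions in one allele's host proteins
#'
#' For each genome's host protein: extract insertion blocks against the
#' intein-free ortholog, apply the size-exclusion filter, and annotate
#' splicing motifs (+1 residue taken from the host sequence just after the
#' block). Candidates failing both terminal splicing motifs are removed, as
#' are blocks outside the size envelope. If a PSSM is supplied, proteins are
#' first screened by [scan_pssm()] and each hit is annotated with the best
#' overlapping window score.
#'
#' @param proteins named character vector of host proteins (names = genome
#'   ids) for one host gene.
#' @param ortholog intein-free ortholog sequence for this host gene.
#' @param allele_id allele identifier attached to the hits.
#' @param config a [detection_config()].
#' @param pssm optional `intein_pssm` used as a pre-screen and for scoring.
#' @return Data frame of hits: `genome`, `allele`, `start`, `end`, `length`,
#'   `seq`, `pssm_score`, `n_terminal_ok`, `c_terminal_ok`, `plus_one_ok`,
#'   `motif_pass`, `provisional`, `anchored`, `truncated`.
#' @export
detect_allele <- function(proteins, ortholog, allele_id,
                          config = detection_config(), pssm = NULL) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  rows <- list()
  for (g in names(proteins)) {
    host <- proteins[[g]]
    windows <- NULL
    if (!is.null(pssm)) {
      windows <- scan_pssm(pssm, host, config$pssm_score_threshold)
      if (nrow(windows) == 0) next
    }
    blocks <- extract_insertion(host, ortholog, config$min_block_len)
    if (nrow(blocks) == 0) next
    keep <- size_filter(blocks$length, config)
    blocks <- blocks[keep, , drop = FALSE]
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      rb <- refine_block(host, b$start, b$end)
      if (rb[["start"]] != b$start || rb[["end"]] != b$end) {
        b$start <- rb[["start"]]
        b$end <- rb[["end"]]
        b$length <- b$end - b$start
        b$seq <- substr(host, b$start + 1L, b$end)
        if (!size_filter(b$length, config)) next
      }
      p1 <- if (b$end < nchar(host)) substr(host, b$end + 1L, b$end + 1L) else NA
      mot <- verify_splicing_motifs(b$seq, p1)
      if (!mot$n_terminal_ok && !mot$c_terminal_ok) next
      sc <- NA_real_
      if (!is.null(windows) && nrow(windows)) {
        ov <- windows$start < b$end & windows$end > b$start
        if (any(ov)) sc <- max(windows$score[ov])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, allele = allele_id, start = b$start, end = b$end,
        length = b$length, seq = b$seq, pssm_score = sc,
        n_terminal_ok = mot$n_terminal_ok, c_terminal_ok = mot$c_terminal_ok,
        plus_one_ok = mot$plus_one_ok, motif_pass = mot$pass,
        provisional = mot$provisional,
        anchored = b$anchored,
        truncated = b$start == 0L || b$end == nchar(host),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome = character(0), allele = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0),
                      pssm_score = numeric(0), n_terminal_ok = logical(0),
                      c_terminal_ok = logical(0), plus_one_ok = logical(0),
                      motif_pass = logical(0), provisional = logical(0),
                      anchored = logical(0), truncated = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Align a sequence to a seed alignment's columns via its consensus
#'
#' Profile-style alignment used when enriching seed alignments with newly
#' detected inteins: the sequence is globally aligned to the alignment's
#' majority-rule consensus, residues are mapped to consensus columns, and
#' residues falling in insertions relative to the profile are discarded (the
#' usual match-state convention), so the alignment width never changes.
#'
#' @param seq amino-acid string.
#' @param seed_alignment existing alignment (any form accepted by
#'   [build_pssm()]).
#' @return A single aligned string of the same width as the seed alignment.
#' @export
align_to_profile <- function(seq, seed_alignment) {
  m <- as_alignment_matrix(seed_alignment)
  cons <- apply(m, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
  anchor_cols <- which(cons != "-")
  anchor <- paste(cons[anchor_cols], collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(seq)),
    subject = Biostrings::AAString(anchor),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  ps <- strsplit(as.character(Biostrings::pattern(pa)), "", fixed = TRUE)[[1]]
  ss <- strsplit(as.character(Biostrings::subject(pa)), "", fixed = TRUE)[[1]]
  row <- rep("-", ncol(m))
  anchor_i <- 0L
  for (k in seq_along(ss)) {
    if (ss[k] != "-") {
      anchor_i <- anchor_i + 1L
      if (ps[k] != "-") row[anchor_cols[anchor_i]] <- ps[k]
    }
  }
  paste(row, collapse = "")
}

#' Iterative detection with seed enrichment
#'
#' One refinement round adds size- and motif-passing hits to the per-allele
#' seed alignments (by profile insertion, see [align_to_profile()]), rebuilds
#' the PSSMs and rescans the corpus. Iteration stops at a fixed point (the hit
#' set no longer changes) or after `max_rounds` rounds, in which case the last
#' hit set is returned with `converged = FALSE`.
#'
#' @param corpus named list per allele of named character vectors of host
#'   proteins.
#' @param seeds named list per allele of seed alignments.
#' @param orthologs named character vector of intein-free ortholog sequences
#'   per allele.
#' @param config a [detection_config()].
#' @param max_rounds maximum refinement rounds.
#' @return A list with `hits` (combined hit data frame), `seeds` (enriched
#'   alignments), `rounds` (rounds executed) and `converged`.
#' @export
iterate_detection <- function(corpus, seeds, orthologs,
                              config = detection_config(), max_rounds = 3L) {
  if (length(seeds) < 1) stopf("need at least one seed alignment")
  alleles <- names(seeds)
  stopifnot(!is.null(alleles), all(alleles %in% names(orthologs)))
  hit_key <- function(h) {
    if (nrow(h) == 0) return(character(0))
    sort(paste(h$allele, h$genome, h$start, h$end))
  }
  prev_key <- NULL
  hits <- NULL
  converged <- FALSE
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    rounds <- round
    all_hits <- list()
    for (a in alleles) {
      prot <- corpus[[a]]
      if (is.null(prot) || !length(prot)) next
      pssm <- build_pssm(seeds[[a]])
      all_hits[[a]] <- detect_allele(prot, orthologs[[a]], a, config, pssm)
    }
    hits <- if (length(all_hits)) do.call(rbind, all_hits) else
      detect_allele(setNames(character(0), character(0)), "", "none", config)
    rownames(hits) <- NULL
    key <- hit_key(hits)
    if (identical(key, prev_key)) { converged <- TRUE; break }
    prev_key <- key
    # enrich seeds with newly found inteins
    for (a in alleles) {
      h <- all_hits[[a]]
      if (is.null(h) || nrow(h) == 0) next
      m <- as_alignment_matrix(seeds[[a]])
      have <- rownames(m)
      for (i in seq_len(nrow(h))) {
        id <- paste0(h$genome[i], "|", a)
        if (!is.null(have) && id %in% have) next
        new_row <- align_to_profile(h$seq[i], m)
        m <- rbind(m, strsplit(new_row, "", fixed = TRUE)[[1]])
        rownames(m)[nrow(m)] <- id
        have <- rownames(m)
      }
      seeds[[a]] <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    }
  }
  if (!converged)
    warning("iterate_detection did not reach a fixed point within max_rounds")
  list(hits = hits, seeds = seeds, rounds = rounds, converged = converged)
}
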