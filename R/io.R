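#' Read a protein FASTA file
#'
#' Wraps `Biostrings::readAAStringSet`. Records are returned as a named
#' character vector (names carry the full header line); lowercase residues
#' are normalised to uppercase with a notice. An empty file yields an empty
#' vector.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stopf("malformed FASTA '%s': %s",
                                          path, conditionMessage(e)))
  s <- toupper(as.character(x))
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")])))
    message("read_fasta: lowercase residues normalised to uppercase")
  setNames(s, names(x))
}

#' Write sequences as FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a single-tree newick file
#'
#' @param path newick file path; must contain exactly one tree. Branch
#'   lengths and internal node labels (supports) are preserved.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stopf("malformed newick '%s': %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stopf("malformed newick '%s'", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stopf("expected a single tree, found %d", length(tr))
    tr <- tr[[1]]
  }
  tr
}

#' Write a tree as newick
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @param digits significant digits used for branch lengths.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  writeLines(ape::write.tree(tree, digits = digits), path)
  invisible(path)
}

# state <-> single-letter cell codes used in wide profile TSVs
.state_codes <- c(ABSENT = "A", MINI = "M", LARGE = "L", MISSING = "?")

#' Write an allele profile as a wide TSV
#'
#' Genomes in rows, alleles in columns, cells coded `A` (absent), `M`
#' (mini), `L` (large), `?` (missing).
#'
#' @param profile an [allele_profile()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "allele_profile"))
  m <- matrix(.state_codes[profile$states], nrow = length(profile$genomes),
              dimnames = dimnames(profile$states))
  d <- data.frame(genome = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide profile TSV written by [write_profile()]
#'
#' @param path TSV path.
#' @return An [allele_profile()] (without lengths).
#' @export
read_profile <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "genome") stopf("profile TSV must start with a 'genome' column")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$genome
  states <- matrix(names(.state_codes)[match(m, .state_codes)],
                   nrow = nrow(m), dimnames = dimnames(m))
  if (anyNA(states)) stopf("invalid profile cell code(s) in '%s'", path)
  allele_profile(states)
}

#' Export a mixed presence-absence + sequence NEXUS matrix
#'
#' Builds the concatenated matrix used for Bayesian clustering of genomes by
#' intein content: one binary column per allele (1 = intein present, mini or
#' large alike; 0 = absent; `?` = missing) followed by one aligned protein
#' block per allele. Genomes absent from an allele's alignment — and all
#' MISSING cells — are padded with `?` across that block. The emitted command
#' block encodes the clustering priors: symmetric Dirichlet with an
#' exponential(1.0) hyperprior and variable coding with 5 beta categories for
#' the binary partition; fixed WAG with gamma rate variation and a proportion
#' of invariant sites for the protein partitions. Run length and sampling
#' settings are left as explicit placeholders.
#'
#' @param profile an [allele_profile()].
#' @param alignments named list per allele of aligned sequences (named by
#'   genome; equal widths within an allele). Alleles without an alignment
#'   contribute only their binary column.
#' @param path output NEXUS path.
#' @return Invisibly, a list describing the partitions (`n_taxa`, `n_char`,
#'   `partitions` data frame with `name`, `from`, `to`).
#' @export
export_mixed_nexus <- function(profile, alignments, path) {
  stopifnot(inherits(profile, "allele_profile"))
  genomes <- profile$genomes
  alleles <- profile$alleles
  alignments <- alignments[intersect(names(alignments), alleles)]
  widths <- integer(0)
  mats <- list()
  for (a in names(alignments)) {
    m <- as_alignment_matrix(alignments[[a]])
    if (is.null(rownames(m))) stopf("alignment rows for '%s' must be named", a)
    extra <- setdiff(rownames(m), genomes)
    if (length(extra))
      stopf("alignment '%s' has rows outside the profile genomes: %s",
            a, paste(extra, collapse = ", "))
    mats[[a]] <- m
    widths[a] <- ncol(m)
  }
  nb <- length(alleles)
  nchar_total <- nb + sum(widths)
  bin <- vapply(seq_along(genomes), function(i) {
    paste(vapply(alleles, function(a) {
      s <- profile$states[i, a]
      if (s == "MISSING") "?" else if (s == "ABSENT") "0" else "1"
    }, ""), collapse = "")
  }, "")
  rows <- bin
  part <- data.frame(name = "presence", from = 1L, to = nb,
                     stringsAsFactors = FALSE)
  pos <- nb
  for (a in names(mats)) {
    m <- mats[[a]]
    w <- ncol(m)
    blk <- vapply(seq_along(genomes), function(i) {
      g <- genomes[i]
      if (profile$states[i, a] != "MISSING" && g %in% rownames(m))
        paste(m[g, ], collapse = "")
      else strrep("?", w)
    }, "")
    rows <- paste0(rows, blk)
    part <- rbind(part, data.frame(name = a, from = pos + 1L, to = pos + w,
                                   stringsAsFactors = FALSE))
    pos <- pos + w
  }
  stopifnot(pos == nchar_total)
  pad <- max(nchar(genomes)) + 2L
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(genomes), nchar_total),
    sprintf(paste0("  FORMAT DATATYPE=MIXED(STANDARD:1-%d%s)",
                   " GAP=- MISSING=? INTERLEAVE=NO;"),
            nb,
            if (nchar_total > nb) sprintf(",PROTEIN:%d-%d", nb + 1L, nchar_total)
            else ""),
    "  MATRIX",
    sprintf("    %-*s%s", pad, genomes, rows),
    "  ;",
    "END;",
    "",
    "BEGIN MRBAYES;",
    sprintf("  charset %s = %d-%d;", part$name, part$from, part$to),
    sprintf("  partition by_block = %d: %s;", nrow(part),
            paste(part$name, collapse = ", ")),
    "  set partition = by_block;",
    "  lset applyto=(1) coding=variable rates=gamma ngammacat=5;",
    "  prset applyto=(1) symdirihyperpr=exponential(1.0);")
  if (nrow(part) > 1) {
    prot_idx <- paste(seq(2L, nrow(part)), collapse = ",")
    lines <- c(lines,
               sprintf("  lset applyto=(%s) rates=invgamma;", prot_idx),
               sprintf("  prset applyto=(%s) aamodelpr=fixed(wag) statefreqpr=dirichlet(1.0);",
                       prot_idx))
  }
  lines <- c(lines,
             "  [ mcmc ngen=<unset> samplefreq=<unset> : set run length before use ]",
             "END;")
  writeLines(lines, path)
  invisible(list(n_taxa = length(genomes), n_char = nchar_total,
                 partitions = part))
}

#' Read back a mixed NEXUS matrix written by [export_mixed_nexus()]
#'
#' A minimal reader for the package's own exporter output, used to verify
#' round-trips; it is not a general NEXUS parser.
#'
#' @param path NEXUS path.
#' @return List with `taxa`, `rows` (full matrix rows as strings),
#'   `partitions` (data frame `name`, `from`, `to`), `binary` (character
#'   matrix of the presence partition) and `blocks` (named list of per-allele
#'   row vectors).
#' @export
read_mixed_nexus <- function(path) {
  ln <- readLines(path)
  if (!length(ln) || ln[1] != "#NEXUS") stopf("not a NEXUS file: %s", path)
  dim_line <- grep("DIMENSIONS", ln, value = TRUE)[1]
  ntax <- as.integer(sub(".*NTAX=(\\d+).*", "\\1", dim_line))
  nchar_total <- as.integer(sub(".*NCHAR=(\\d+).*", "\\1", dim_line))
  mstart <- grep("^\\s*MATRIX\\s*$", ln)[1]
  rows <- ln[(mstart + 1L):(mstart + ntax)]
  sp <- regmatches(rows, regexpr("^\\s*\\S+", rows))
  taxa <- trimws(sp)
  data <- trimws(substring(rows, nchar(sp) + 1L))
  if (any(nchar(data) != nchar_total))
    stopf("matrix rows do not match NCHAR=%d", nchar_total)
  cs <- grep("^\\s*charset ", ln, value = TRUE)
  partitions <- data.frame(
    name = sub("^\\s*charset (\\S+) = .*", "\\1", cs),
    from = as.integer(sub(".* = (\\d+)-(\\d+);", "\\1", cs)),
    to = as.integer(sub(".* = (\\d+)-(\\d+);", "\\2", cs)),
    stringsAsFactors = FALSE)
  bin_part <- partitions[partitions$name == "presence", ]
  binary <- do.call(rbind, strsplit(substring(data, bin_part$from, bin_part$to),
                                    "", fixed = TRUE))
  rownames(binary) <- taxa
  blocks <- list()
  for (i in seq_len(nrow(partitions))) {
    if (partitions$name[i] == "presence") next
    blocks[[partitions$name[i]]] <-
      setNames(substring(data, partitions$from[i], partitions$to[i]), taxa)
  }
  list(taxa = taxa, rows = setNames(data, taxa), partitions = partitions,
       binary = binary, blocks = blocks)
}

#' Run the full simulate -> detect -> classify -> analyse pipeline
#'
#' Simulates an intein survey, recovers the inteins from the simulated
#' proteins by ortholog comparison (optionally PSSM-screened), assigns
#' mini/large states by the length-gap rule, merges the per-cell states into
#' a profile, screens the alleles for vertical compatibility on the true
#' species tree, and scores the recovered profile against the simulation
#' truth on unmasked cells. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (overrides `config$seed` when given).
#' @param out_dir optional output directory; when given, the fixture files,
#'   the recovered profile TSV, a plain-text report and a run manifest are
#'   written there.
#' @param detection a [detection_config()].
#' @param use_pssm if `TRUE`, detection is additionally screened through a
#'   PSSM built from the true intein sequences of each allele.
#' @return List with `truth`, `hits`, `profile` (recovered), `vertical`
#'   (from [vertical_compatibility()]), `agreement` (fraction of unmasked
#'   cells where the recovered state equals the truth), `files`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_taxa = 8, n_alleles = 2), seed = 42)
#' res$agreement
#' }
run_pipeline <- function(config = sim_config(), seed = NULL, out_dir = NULL,
                         detection = detection_config(), use_pssm = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) stopf("a seed is required for a reproducible run")
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa, config$birth_rate)
  cfg2 <- config
  cfg2$seed <- NULL   # continue the RNG stream started above
  truth <- simulate_homing(tree, cfg2, evolve_sequences = TRUE)

  alleles <- colnames(truth$full_states)
  genomes <- tree$tip.label
  hits <- list()
  for (a in alleles) {
    pssm <- NULL
    if (use_pssm) {
      tr_seqs <- truth$coords[truth$coords$allele == a, ]
      if (nrow(tr_seqs) >= 2) {
        seqs <- vapply(seq_len(nrow(tr_seqs)), function(i) {
          substr(truth$proteins[[a]][[tr_seqs$genome[i]]],
                 tr_seqs$start[i] + 1L, tr_seqs$end[i])
        }, "")
        seqs <- seqs[nchar(seqs) == max(nchar(seqs))]
        if (length(seqs) >= 2) pssm <- build_pssm(setNames(seqs, seq_along(seqs)))
      }
    }
    hits[[a]] <- detect_allele(truth$proteins[[a]], truth$ancestral_exteins[[a]],
                               a, detection, pssm)
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL

  assignments <- list()
  for (a in alleles) {
    h <- hits[hits$allele == a & !hits$truncated, , drop = FALSE]
    assignments[[a]] <- if (nrow(h))
      assign_states(setNames(h$length, h$genome)) else character(0)
  }
  presence <- !truth$masked   # host gene found wherever the cell is unmasked
  profile <- merge_states(hits, assignments, genomes, presence)
  vertical <- vertical_compatibility(tree, profile)
  unmasked <- !truth$masked
  agreement <- mean(profile$states[unmasked] == truth$full_states[unmasked])

  files <- character(0)
  if (!is.null(out_dir)) {
    files <- emit_fixture(truth, out_dir)
    f <- file.path(out_dir, "recovered_profile.tsv")
    write_profile(profile, f)
    files["recovered_profile"] <- f
    rep_lines <- c(
      "intein pipeline report",
      sprintf("seed: %d", config$seed),
      sprintf("genomes: %d  alleles: %d", length(genomes), length(alleles)),
      sprintf("hits: %d", nrow(hits)),
      sprintf("state agreement with truth (unmasked cells): %.4f", agreement),
      sprintf("vertically compatible alleles: %d/%d",
              sum(vertical$compatible), length(vertical$compatible)))
    f <- file.path(out_dir, "report.txt")
    writeLines(rep_lines, f)
    files["report"] <- f
    man <- c(
      sprintf("package: inteinflow %s",
              as.character(utils::packageVersion("inteinflow"))),
      sprintf("R: %s", R.version.string),
      sprintf("seed: %d", config$seed),
      sprintf("n_taxa: %d  n_alleles: %d  n_slices: %d",
              config$n_taxa, config$n_alleles, config$n_slices),
      sprintf("rates: invasion=%g transfer=%g decay_lambda=%g hen_loss=%g deletion=%g",
              config$invasion_rate, config$transfer_rate, config$decay_lambda,
              config$hen_loss_rate, config$deletion_rate),
      sprintf("mu_extein: %g  mu_intein: %g", config$mu_extein, config$mu_intein),
      sprintf("records: events=%d hits=%d cells=%d",
              nrow(truth$events), nrow(hits),
              length(genomes) * length(alleles)))
    f <- file.path(out_dir, "manifest.txt")
    writeLines(man, f)
    files["manifest"] <- f
  }
  list(truth = truth, hits = hits, profile = profile, vertical = vertical,
       agreement = agreement, files = files)
}
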