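#' Load the reference catalog of halobacterial intein alleles
#'
#' The package ships a transcription of the published survey catalog of
#' intein alleles in the Halobacteria: one row per intein allele (a specific
#' insertion position in a specific host gene) with the host-gene annotation
#' and novelty flags (`new_allele`: first reported by that survey;
#' `new_host_gene`: the host protein itself had not previously been reported
#' to carry an intein).
#'
#' @param path optional path to an alternative catalog TSV with the same
#'   columns.
#' @return Data frame with columns `allele`, `host_gene`, `extein_annotation`,
#'   `new_allele`, `new_host_gene`.
#' @export
load_intein_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "halobacteria_intein_catalog.tsv",
                        package = "inteinflow")
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$new_allele <- as.logical(d$new_allele)
  d$new_host_gene <- as.logical(d$new_host_gene)
  d
}

#' Load the per-allele tree-topology and taxonomic-distribution table
#'
#' One row per intein allele: the monophyly classification of the
#' halobacterial sequences in that allele's tree (`Monophyletic`,
#' `Polyphyletic-bacteria` or `Polyphyletic-Euryarchaeota`) and the number of
#' member sequences per taxonomic group.
#'
#' @param path optional path to an alternative TSV with the same columns.
#' @return Data frame with columns `allele`, `topology`, `halobacteria`,
#'   `bacteria`, `other_euryarchaeota`.
#' @export
load_allele_topologies <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "halobacteria_allele_topologies.tsv",
                        package = "inteinflow")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load the table of non-halobacterial intein matches
#'
#' One row per intein sequence found outside the Halobacteria that matches a
#' halobacterial allele: species, accession, phylum, whether the sequence is
#' a mini-intein, and whether it groups inside the halobacterial sequences on
#' the allele tree.
#'
#' @param path optional path to an alternative TSV with the same columns.
#' @return Data frame with columns `allele`, `species`, `accession`,
#'   `phylum`, `mini`, `groups_within_halobacteria`.
#' @export
load_external_hits <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "halobacteria_external_inteins.tsv",
                        package = "inteinflow")
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$mini <- as.logical(d$mini)
  d$groups_within_halobacteria <- as.logical(d$groups_within_halobacteria)
  d
}

#' Load a genome annotation table, if one is supplied
#'
#' Genome-level survey claims (total genome count, genus representation)
#' require the survey's genome list, which is not distributed with the
#' package. When no path is given this returns `NULL` and no genome-level
#' summary can be computed.
#'
#' @param path path to a TSV with columns `genome`, `genus` (and optionally
#'   `group`), or `NULL`.
#' @return The annotation data frame, or `NULL` when `path` is `NULL`.
#' @export
load_genome_table <- function(path = NULL) {
  if (is.null(path)) return(NULL)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome", "genus") %in% names(d)))
    stopf("genome table must have columns 'genome' and 'genus'")
  if (anyDuplicated(d$genome)) stopf("duplicate genome ids in genome table")
  d
}

#' Summarise a genome annotation table
#'
#' @param genome_table data frame from [load_genome_table()] (non-`NULL`).
#' @return List with `n_genomes`, `n_genera`, `top_genus` and
#'   `pct_top_genus` (nearest-integer percent of genomes in the most
#'   represented genus).
#' @export
genome_survey_summary <- function(genome_table) {
  if (is.null(genome_table))
    stopf("no genome table supplied; genome-level summaries are unavailable")
  tb <- table(genome_table$genus)
  list(n_genomes = nrow(genome_table),
       n_genera = length(tb),
       top_genus = names(tb)[which.max(tb)],
       pct_top_genus = round(100 * max(tb) / nrow(genome_table)))
}

#' Summary counts for an allele catalog
#'
#' @param catalog data frame with columns `allele`, `host_gene`,
#'   `new_allele`, `new_host_gene` (as from [load_intein_catalog()]); rows
#'   are de-duplicated by allele first.
#' @return List with `n_alleles`, `n_host_genes`, `n_new_alleles`,
#'   `n_new_host_genes`.
#' @export
#' @examples
#' catalog_summary(load_intein_catalog())
catalog_summary <- function(catalog) {
  if (is.null(catalog) || nrow(catalog) == 0) stopf("catalog is empty")
  catalog <- catalog[!duplicated(catalog$allele), , drop = FALSE]
  if (any(catalog$new_host_gene & !catalog$new_allele))
    stopf("invalid catalog: a new host gene implies a new allele")
  list(n_alleles = nrow(catalog),
       n_host_genes = length(unique(catalog$host_gene)),
       n_new_alleles = sum(catalog$new_allele),
       n_new_host_genes = length(unique(catalog$host_gene[catalog$new_host_gene])))
}

#' Tally one allele's member sequences by taxonomic group
#'
#' @param ids member sequence/genome ids of one allele.
#' @param annotation data frame with columns `id` and `group` (and optionally
#'   `genus`); every id must be annotated.
#' @return Named integer vector of per-group counts (all groups present in
#'   the annotation, zero-filled), with `sum` equal to `length(ids)`.
#' @export
group_tally <- function(ids, annotation) {
  stopifnot(all(c("id", "group") %in% names(annotation)))
  if (anyDuplicated(annotation$id)) stopf("ids annotated more than once")
  m <- match(ids, annotation$id)
  if (anyNA(m))
    stopf("unannotated id(s): %s", paste(ids[is.na(m)], collapse = ", "))
  groups <- sort(unique(annotation$group))
  tab <- table(factor(annotation$group[m], levels = groups))
  setNames(as.integer(tab), groups)
}

#' Per-genus sequence density of one intein allele
#'
#' The density of a genus in an allele is the number of member sequences from
#' that genus divided by the total number of sequences in the allele; the
#' densities sum to 1 and the number of represented genera is reported
#' alongside.
#'
#' @param ids member sequence/genome ids of one allele (non-empty).
#' @param annotation data frame with columns `id` and `genus`.
#' @return List with `proportions` (named, decreasing, summing to 1),
#'   `n_genera` and `n_sequences`.
#' @export
density_profile <- function(ids, annotation) {
  if (!length(ids)) stopf("allele membership is empty")
  stopifnot(all(c("id", "genus") %in% names(annotation)))
  m <- match(ids, annotation$id)
  if (anyNA(m))
    stopf("unannotated id(s): %s", paste(ids[is.na(m)], collapse = ", "))
  tab <- table(annotation$genus[m])
  prop <- sort(tab / length(ids), decreasing = TRUE)
  list(proportions = setNames(as.numeric(prop), names(prop)),
       n_genera = length(tab), n_sequences = length(ids))
}

#' Headline summary statistics of an intein survey
#'
#' Computes the percentage of allele trees whose focal (halobacterial)
#' sequences are monophyletic, the number of polyphyletic alleles broken down
#' by interrupting group, and — when a state profile is given — the
#' percentage of genomes carrying two or more inteins (MINI and LARGE alike;
#' MISSING ignored). Percentages are rounded to the nearest integer.
#'
#' @param topology character vector of per-allele topology labels, either
#'   `"Monophyletic"` or `"Polyphyletic-<group>"` (case-insensitive on the
#'   prefix).
#' @param interrupting_groups optional character vector overriding the groups
#'   parsed from the polyphyletic labels.
#' @param profile optional [allele_profile()].
#' @return List with `n_alleles`, `pct_monophyletic`, `n_polyphyletic`,
#'   `interrupting_counts` (named integer) and `pct_multi_allele` (`NA`
#'   without a profile).
#' @export
#' @examples
#' headline_stats(load_allele_topologies()$topology)
headline_stats <- function(topology, interrupting_groups = NULL,
                           profile = NULL) {
  if (!length(topology)) stopf("no topology labels supplied")
  mono <- grepl("^mono", topology, ignore.case = TRUE)
  poly <- topology[!mono]
  if (is.null(interrupting_groups))
    interrupting_groups <- sub("^[Pp]olyphyletic-?", "", poly)
  counts <- if (length(interrupting_groups)) {
    tb <- table(tolower(interrupting_groups))
    setNames(as.integer(tb), names(tb))
  } else {
    integer(0)
  }
  pct_multi <- NA_real_
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "allele_profile"))
    n_carried <- rowSums(profile$states == "MINI" | profile$states == "LARGE")
    pct_multi <- round(100 * mean(n_carried >= 2))
  }
  list(n_alleles = length(topology),
       pct_monophyletic = round(100 * mean(mono)),
       n_polyphyletic = sum(!mono),
       interrupting_counts = counts,
       pct_multi_allele = pct_multi)
}
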