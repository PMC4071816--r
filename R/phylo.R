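#' Tree-analysis configuration
#'
#' @param support_threshold internal nodes with bootstrap support below this
#'   value (default 70) are treated as unresolved by
#'   [collapse_low_support()].
#' @param vertical_max_events maximum Fitch change count compatible with
#'   vertical inheritance (default 1: a single gain, no losses).
#' @return A `phylo_config` list.
#' @export
phylo_config <- function(support_threshold = 70, vertical_max_events = 1L) {
  if (support_threshold < 0 || support_threshold > 100)
    stopf("support_threshold must be in [0, 100]")
  if (vertical_max_events < 0) stopf("vertical_max_events must be >= 0")
  structure(list(support_threshold = support_threshold,
                 vertical_max_events = as.integer(vertical_max_events)),
            class = "phylo_config")
}

# Internal: list over all nodes of the tip indices they subtend
# (a tip subtends itself).
tip_descendants <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  ed <- reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    desc[[ed[k, 1]]] <- c(desc[[ed[k, 1]]], desc[[ed[k, 2]]])
  desc
}

#' Collapse poorly supported internal edges into polytomies
#'
#' Every internal edge whose child node carries a numeric support below
#' `threshold` is contracted (its children reattach to its parent, keeping
#' their own branch lengths). Nodes without a numeric support label are kept.
#' The leaf set is unchanged.
#'
#' @param tree a `phylo` tree with supports stored as internal node labels.
#' @param threshold support threshold (same scale as the labels, typically
#'   0-100 bootstrap percentages).
#' @return The collapsed `phylo` tree.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)59:1,(C:1,D:1)95:1);")
#' collapse_low_support(tr, 70)
collapse_low_support <- function(tree, threshold = 70) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(tree)
  nt <- length(tree$tip.label)
  root <- nt + 1L
  sup <- suppressWarnings(as.numeric(tree$node.label))
  drop_node <- rep(FALSE, nt + tree$Nnode)
  for (j in seq_len(tree$Nnode)) {
    node <- nt + j
    if (node != root && !is.na(sup[j]) && sup[j] < threshold)
      drop_node[node] <- TRUE
  }
  if (!any(drop_node)) return(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  len_in <- rep(NA_real_, nt + tree$Nnode)
  if (has_len) len_in[tree$edge[, 2]] <- tree$edge.length
  node_lab <- function(node) {
    l <- tree$node.label[node - nt]
    if (is.na(l)) "" else l
  }
  expand_kids <- function(node) {
    out <- integer(0)
    for (c in children[[as.character(node)]]) {
      if (c > nt && drop_node[c]) out <- c(out, expand_kids(c))
      else out <- c(out, c)
    }
    out
  }
  part <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    kids <- expand_kids(node)
    inner <- vapply(kids, function(k) {
      paste0(part(k),
             if (has_len) paste0(":", sprintf("%.10g", len_in[k])) else "")
    }, "")
    paste0("(", paste(inner, collapse = ","), ")", node_lab(node))
  }
  ape::read.tree(text = paste0(part(root), ";"))
}

#' Classify a focal leaf set as monophyletic or polyphyletic (unrooted)
#'
#' The tree is read as unrooted: the focal set is monophyletic when some edge
#' bipartition separates exactly the focal leaves from the rest. Polytomies
#' are treated permissively — a focal/rest split achievable by resolving a
#' polytomy counts as monophyletic (equivalently: some vertex exists all of
#' whose incident subtrees are purely focal or purely non-focal).
#'
#' For polyphyletic sets, the interrupting leaves are the smallest set of
#' non-focal leaves entangled with the focal spanning subtree: over all
#' internal vertices, the minimum (ties broken toward the lexicographically
#' smallest label set) of the non-focal leaves sitting in focal-containing
#' components. Their majority group annotation is reported as the
#' interrupting group (ties report all tied groups).
#'
#' @param tree a `phylo` tree with at least 3 leaves.
#' @param focal character vector of focal leaf labels (non-empty subset of
#'   the leaves).
#' @param groups optional named character map leaf label -> group annotation.
#' @param support_threshold if non-`NULL`, [collapse_low_support()] is applied
#'   first with this threshold.
#' @return An object of class `monophyly_result`: `classification`
#'   (`"monophyletic"`/`"polyphyletic"`), `interrupting_labels`,
#'   `interrupting_group` (`"none"` when monophyletic, `NA` without a group
#'   map; possibly several tied groups), `degenerate` (`TRUE` when focal was
#'   the full leaf set).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,C),(B,D));")
#' monophyly_class(tr, c("A", "B"))
monophyly_class <- function(tree, focal, groups = NULL,
                            support_threshold = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(support_threshold))
    tree <- collapse_low_support(tree, support_threshold)
  tips <- tree$tip.label
  nt <- length(tips)
  if (nt < 3) stopf("tree must have at least 3 leaves")
  focal <- unique(focal)
  if (!length(focal)) stopf("focal set must be non-empty")
  missing <- setdiff(focal, tips)
  if (length(missing))
    stopf("focal leaves not in tree: %s", paste(missing, collapse = ", "))
  if (setequal(focal, tips))
    return(structure(list(classification = "monophyletic",
                          interrupting_labels = character(0),
                          interrupting_group = "none", degenerate = TRUE),
                     class = "monophyly_result"))
  desc <- tip_descendants(tree)
  infocal <- tips %in% focal
  children <- split(tree$edge[, 2], tree$edge[, 1])
  all_tips <- seq_len(nt)
  best_key <- NULL
  best_set <- NULL
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    comps <- lapply(children[[as.character(v)]], function(c) desc[[c]])
    rest <- setdiff(all_tips, desc[[v]])
    if (length(rest)) comps <- c(comps, list(rest))
    nf <- vapply(comps, function(s) sum(infocal[s]), 0L)
    pure <- nf == 0L | nf == lengths(comps)
    if (all(pure))
      return(structure(list(classification = "monophyletic",
                            interrupting_labels = character(0),
                            interrupting_group = "none", degenerate = FALSE),
                       class = "monophyly_result"))
    extra <- unlist(comps[nf > 0L])
    extra <- sort(tips[extra[!infocal[extra]]])
    key <- paste(extra, collapse = "\r")
    if (is.null(best_set) || length(extra) < length(best_set) ||
        (length(extra) == length(best_set) && key < best_key)) {
      best_set <- extra
      best_key <- key
    }
  }
  grp <- NA_character_
  if (!is.null(groups)) {
    g <- groups[best_set]
    g <- g[!is.na(g)]
    if (length(g)) {
      tb <- table(g)
      grp <- sort(names(tb)[tb == max(tb)])
    }
  }
  structure(list(classification = "polyphyletic",
                 interrupting_labels = best_set,
                 interrupting_group = grp, degenerate = FALSE),
            class = "monophyly_result")
}

#' @export
print.monophyly_result <- function(x, ...) {
  cat("monophyly_result:", x$classification)
  if (x$classification == "polyphyletic")
    cat(sprintf(" (interrupted by %s: %s)",
                paste(x$interrupting_group, collapse = "/"),
                paste(x$interrupting_labels, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Minimum-change parsimony count for a binary character
#'
#' Small-parsimony (Sankoff) minimum number of 0/1 state changes the tree
#' requires to explain the leaf states; the count is independent of rooting.
#' Leaves with `NA` states are pruned before counting; polytomies are
#' handled exactly.
#'
#' @param tree a `phylo` tree.
#' @param character named vector over (a subset of) the leaf labels, with
#'   values 0/1 (numeric, logical or character); leaves absent from the
#'   vector, or `NA`, are pruned.
#' @return Integer: the minimum number of changes.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_events(tr, c(A = 1, B = 0, C = 1, D = 0))
fitch_events <- function(tree, character) {
  stopifnot(inherits(tree, "phylo"))
  ch <- character
  if (is.logical(ch)) ch <- as.integer(ch)
  if (is.character(ch)) {
    nm <- names(ch)
    ch <- suppressWarnings(as.integer(ch))
    names(ch) <- nm
  }
  if (is.null(names(ch))) stopf("character must be named by leaf label")
  x <- ch[tree$tip.label]
  retained <- tree$tip.label[!is.na(x)]
  if (length(retained) < 2)
    stopf("fewer than 2 leaves carry an observed state")
  if (length(retained) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, retained)
  x <- ch[tree$tip.label]
  if (!all(x %in% c(0L, 1L))) stopf("character states must be 0 or 1")
  nt <- length(tree$tip.label)
  inf <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, nt + tree$Nnode, 2L)
  cost[cbind(seq_len(nt), 1L)] <- ifelse(x == 0L, 0L, inf)
  cost[cbind(seq_len(nt), 2L)] <- ifelse(x == 1L, 0L, inf)
  ed <- reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1]; c <- ed[k, 2]
    cost[p, 1L] <- cost[p, 1L] + min(cost[c, 1L], cost[c, 2L] + 1L)
    cost[p, 2L] <- cost[p, 2L] + min(cost[c, 2L], cost[c, 1L] + 1L)
  }
  min(cost[nt + 1L, ])
}

#' Screen alleles for compatibility with vertical inheritance
#'
#' An allele's presence character (MINI/LARGE = 1, ABSENT = 0, MISSING
#' pruned) is mapped onto the reference tree; the allele is vertically
#' compatible when its Fitch change count does not exceed
#' `vertical_max_events`. Alleles with fewer than two informative leaves are
#' trivially compatible (0 events).
#'
#' @param tree reference `phylo` tree whose leaves cover the profile genomes.
#' @param profile an [allele_profile()].
#' @param config a [phylo_config()].
#' @return List with `events` (named integer per allele), `compatible`
#'   (named logical) and `fraction` (proportion compatible).
#' @export
vertical_compatibility <- function(tree, profile, config = phylo_config()) {
  stopifnot(inherits(profile, "allele_profile"))
  missing <- setdiff(profile$genomes, tree$tip.label)
  if (length(missing))
    stopf("profile genomes not on the tree: %s", paste(missing, collapse = ", "))
  events <- vapply(profile$alleles, function(a) {
    st <- profile$states[, a]
    chr <- ifelse(st == "MISSING", NA_integer_,
                  as.integer(st %in% c("MINI", "LARGE")))
    names(chr) <- profile$genomes
    ok <- !is.na(chr)
    if (sum(ok) < 2 || length(unique(chr[ok])) == 1) return(0L)
    fitch_events(tree, chr)
  }, 0L)
  compatible <- events <= config$vertical_max_events
  list(events = events, compatible = compatible,
       fraction = mean(compatible))
}

#' Count alleles shared by every member of a genome set
#'
#' @param profile an [allele_profile()].
#' @param members character vector of at least two profile genomes.
#' @param strict in strict mode (default) a MISSING cell disqualifies the
#'   allele; otherwise MISSING members are ignored provided at least one
#'   member carries the intein and no member is ABSENT.
#' @return Integer count of shared alleles.
#' @export
shared_alleles <- function(profile, members, strict = TRUE) {
  stopifnot(inherits(profile, "allele_profile"))
  unknown <- setdiff(members, profile$genomes)
  if (length(unknown))
    stopf("unknown genome(s): %s", paste(unknown, collapse = ", "))
  if (length(members) < 2) stopf("need at least two members")
  st <- profile$states[members, , drop = FALSE]
  shared <- apply(st, 2, function(col) {
    if (strict) all(col %in% c("MINI", "LARGE"))
    else all(col != "ABSENT") && any(col %in% c("MINI", "LARGE"))
  })
  sum(shared)
}
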