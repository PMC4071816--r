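# Shared fixtures and independent oracles used across the test files.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# Point-mutate a fraction of residues (never touching `protect`, 1-based).
mutate_protein <- function(seq, frac, protect = integer(0)) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- setdiff(which(runif(length(v)) < frac), protect)
  for (i in idx) v[i] <- sample(setdiff(aa20, v[i]), 1)
  paste(v, collapse = "")
}

# A founder intein with canonical splicing residues.
make_founder_intein <- function(len) {
  v <- sample(aa20, len, replace = TRUE)
  v[1] <- sample(c("C", "S", "A"), 1)
  v[len - 1] <- "H"
  v[len] <- sample(c("N", "Q"), 1)
  paste(v, collapse = "")
}

# Brute-force minimum-change parsimony: enumerate all internal labelings.
fitch_brute <- function(tree, chr) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- chr[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    st <- c(x, as.integer(intToBits(mask))[seq_len(nn)])
    best <- min(best, sum(st[tree$edge[, 1]] != st[tree$edge[, 2]]))
  }
  best
}

# Independent monophyly oracle on binary trees: exhaustive edge-bipartition
# enumeration via ape::prop.part.
mono_oracle <- function(tree, focal) {
  labs <- tree$tip.label
  if (length(focal) <= 1 || length(focal) >= length(labs) - 1) return(TRUE)
  pp <- ape::prop.part(tree)
  pl <- attr(pp, "labels")
  any(vapply(pp, function(cl) {
    s <- pl[cl]
    setequal(s, focal) || setequal(setdiff(labs, s), focal)
  }, TRUE))
}

# Small allele profile built directly from a presence list.
profile_from_sets <- function(sets, alleles) {
  genomes <- names(sets)
  st <- matrix("ABSENT", length(genomes), length(alleles),
               dimnames = list(genomes, alleles))
  for (g in genomes) st[g, intersect(sets[[g]], alleles)] <- "LARGE"
  allele_profile(st)
}
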