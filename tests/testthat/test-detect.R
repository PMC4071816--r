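test_that("PSSM log-odds match closed forms", {
  # a column using each residue exactly once equals a uniform background:
  # score 0 for every residue regardless of pseudocount weight
  set.seed(1)
  aln <- vapply(seq_len(20), function(i) {
    paste0(aa20[i], paste(sample(aa20, 4, replace = TRUE), collapse = ""))
  }, "")
  names(aln) <- paste0("s", 1:20)
  p <- build_pssm(aln, pseudocount_weight = 1)
  expect_equal(unname(p$scores[, 1]), rep(0, 20), tolerance = 1e-12)

  # all-C column, uniform background, vanishing pseudocounts:
  # score(C) -> log2(1 / 0.05) ~ 4.32 bits
  aln2 <- c(a = "CA", b = "CC", c = "CG")
  p2 <- build_pssm(aln2, pseudocount_weight = 1e-9)
  expect_equal(unname(p2$scores["C", 1]), log2(20), tolerance = 1e-6)

  expect_error(build_pssm(c(a = "ACD")), "2 aligned")
  expect_error(build_pssm(c(a = "ACD", b = "AC")), "same length")
})

test_that("gap-majority columns are dropped and recorded", {
  aln <- c(a = "A-CA", b = "A-CC", c = "A--G", d = "A-CT")
  p <- build_pssm(aln)
  expect_equal(p$dropped_columns, 2L)
  expect_equal(p$length, 3L)
})

test_that("seed sequences outscore their residue-shuffled nulls", {
  set.seed(42)
  founder <- make_founder_intein(120)
  seeds <- setNames(vapply(1:5, function(i) mutate_protein(founder, 0.1), ""),
                    paste0("s", 1:5))
  p <- build_pssm(seeds)
  for (s in seeds) {
    own <- pssm_score(p, s)
    shuf <- vapply(1:100, function(i) {
      pssm_score(p, paste(sample(strsplit(s, "")[[1]]), collapse = ""))
    }, 0)
    expect_gt(own, mean(shuf))
  }
})

test_that("scanning the consensus hits the maximum attainable score at 0", {
  set.seed(7)
  seeds <- setNames(vapply(1:4, function(i) random_protein(60), ""),
                    paste0("s", 1:4))
  p <- build_pssm(seeds)
  hits <- scan_pssm(p, p$consensus, threshold = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$score, p$max_score, tolerance = 1e-9)

  # single-residue mutation at a consensus column can only lower the score
  v <- strsplit(p$consensus, "")[[1]]
  v[10] <- setdiff(aa20, v[10])[1]
  expect_lt(pssm_score(p, paste(v, collapse = "")), p$max_score)

  # protein shorter than the PSSM: empty result, not an error
  expect_equal(nrow(scan_pssm(p, "ACDEF", 0)), 0L)
})

test_that("random background proteins essentially never reach +10 bits", {
  set.seed(13)
  founder <- make_founder_intein(450)
  seeds <- setNames(vapply(1:5, function(i) mutate_protein(founder, 0.1), ""),
                    paste0("s", 1:5))
  p <- build_pssm(seeds)
  total <- 0L
  for (i in 1:100) {
    total <- total + nrow(scan_pssm(p, random_protein(500), threshold = 10))
  }
  expect_lte(total, 1L)
})

test_that("planted diverged inteins are recovered by scanning", {
  set.seed(99)
  founder <- make_founder_intein(450)
  seeds <- setNames(vapply(1:5, function(i) mutate_protein(founder, 0.1), ""),
                    paste0("s", 1:5))
  p <- build_pssm(seeds)
  found <- 0L
  for (rep in 1:50) {
    ext <- random_protein(400)
    pos <- sample(50:350, 1)
    copy <- mutate_protein(founder, 0.15)
    host <- paste0(substr(ext, 1, pos), copy, substr(ext, pos + 1, 400))
    h <- scan_pssm(p, host, threshold = 10)
    if (nrow(h) && any(h$start < pos + 450 & h$end > pos)) found <- found + 1L
  }
  expect_gte(found, 48L)                        # >= 95% of 50 replicates
})

test_that("extract_insertion recovers planted blocks exactly", {
  set.seed(3)
  orth <- random_protein(500)
  block <- random_protein(400)
  host <- paste0(substr(orth, 1, 250), block, substr(orth, 251, 500))
  b <- extract_insertion(host, orth, min_block_len = 50)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 250L)
  expect_equal(b$end, 650L)
  expect_true(b$anchored)
  expect_equal(b$seq, block)

  expect_equal(nrow(extract_insertion(orth, orth)), 0L)

  two <- paste0(substr(orth, 1, 100), random_protein(150),
                substr(orth, 101, 350), random_protein(500),
                substr(orth, 351, 500))
  b2 <- extract_insertion(two, orth, min_block_len = 50)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$length, c(150L, 500L))
  expect_equal(b2$start[1], 100L)
})

test_that("the size-exclusion window is closed at 100 and 700", {
  cfg <- detection_config()
  expect_true(size_filter(400, cfg))
  expect_true(size_filter(100, cfg))
  expect_true(size_filter(700, cfg))
  expect_false(size_filter(99, cfg))
  expect_false(size_filter(701, cfg))
  expect_error(size_filter(-1, cfg), "block_length")
})

test_that("splicing-motif rules follow the canonical block descriptions", {
  m <- verify_splicing_motifs(paste0("C", strrep("A", 50), "HN"), "S")
  expect_true(m$pass)
  expect_false(m$provisional)

  m2 <- verify_splicing_motifs(paste0("M", strrep("A", 50), "KK"), "S")
  expect_false(m2$n_terminal_ok)
  expect_false(m2$c_terminal_ok)
  expect_false(m2$pass)

  m3 <- verify_splicing_motifs(paste0("S", strrep("A", 50), "HQ"), NA)
  expect_true(m3$pass)
  expect_true(m3$provisional)
  expect_true(is.na(m3$plus_one_ok))

  expect_error(verify_splicing_motifs(""), "non-empty")
})

test_that("coordinate recovery on simulated genomes is near-exact", {
  n_ok <- 0L
  n_cells <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_taxa = 6, n_alleles = 2, seed = 400 + s)
    tr <- simulate_tree(6, 1, seed = 400 + s)
    truth <- simulate_homing(tr, cfg)
    for (a in colnames(truth$full_states)) {
      hits <- detect_allele(truth$proteins[[a]], truth$ancestral_exteins[[a]],
                            a, detection_config())
      tc <- truth$coords[truth$coords$allele == a, ]
      for (i in seq_len(nrow(tc))) {
        if (!(tc$genome[i] %in% names(truth$proteins[[a]]))) next
        n_cells <- n_cells + 1L
        h <- hits[hits$genome == tc$genome[i], ]
        if (nrow(h) == 1 && abs(h$start - tc$start[i]) <= 2 &&
            abs(h$end - tc$end[i]) <= 2) n_ok <- n_ok + 1L
      }
    }
  }
  expect_gte(n_ok / n_cells, 0.9)
})

test_that("iterated detection is idempotent at its fixed point", {
  set.seed(17)
  founder <- make_founder_intein(300)
  seeds <- list(al1 = setNames(vapply(1:4, function(i)
    mutate_protein(founder, 0.05, protect = c(1, 299, 300)), ""),
    paste0("s", 1:4)))
  orth <- random_protein(400)
  corpus <- list(al1 = setNames(vapply(1:3, function(i) {
    paste0(substr(orth, 1, 200),
           mutate_protein(founder, 0.05, protect = c(1, 299, 300)),
           substr(orth, 201, 400))
  }, ""), paste0("g", 1:3)))
  res <- iterate_detection(corpus, seeds, c(al1 = orth), max_rounds = 4)
  expect_true(res$converged)
  expect_equal(sort(unique(res$hits$genome)), c("g1", "g2", "g3"))
  expect_equal(nrow(res$hits), 3L)

  # empty corpus: no hits, seeds unchanged
  res0 <- iterate_detection(list(al1 = character(0)), seeds, c(al1 = orth))
  expect_equal(nrow(res0$hits), 0L)
  expect_identical(res0$seeds, seeds)
})

test_that("seed enrichment recovers a diverged intein in a second round", {
  set.seed(23)
  founder <- make_founder_intein(300)
  prot <- c(1, 299, 300)
  near <- mutate_protein(founder, 0.25, protect = prot)
  far <- mutate_protein(near, 0.25, protect = prot)
  seeds <- list(al1 = setNames(vapply(1:4, function(i)
    mutate_protein(founder, 0.03, protect = prot), ""), paste0("s", 1:4)))
  orth <- random_protein(400)
  embed <- function(x) paste0(substr(orth, 1, 200), x, substr(orth, 201, 400))
  corpus <- list(al1 = c(gnear = embed(near), gfar = embed(far)))
  p <- build_pssm(seeds$al1)
  thr <- (pssm_score(p, near) + pssm_score(p, far)) / 2
  cfg <- detection_config(pssm_score_threshold = thr)
  r1 <- detect_allele(corpus$al1, orth, "al1", cfg, p)
  expect_equal(r1$genome, "gnear")              # the far copy is missed alone
  res <- iterate_detection(corpus, seeds, c(al1 = orth), cfg, max_rounds = 4)
  expect_setequal(res$hits$genome, c("gnear", "gfar"))
})
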