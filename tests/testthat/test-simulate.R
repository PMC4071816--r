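test_that("simulate_tree yields deterministic ultrametric labelled trees", {
  expect_error(simulate_tree(1), "n_taxa")

  tr2 <- simulate_tree(2, 1, seed = 7)
  expect_s3_class(tr2, "phylo")
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[1], d[2])                      # both root-to-tip paths equal

  a <- ape::write.tree(simulate_tree(8, 1, seed = 1))
  b <- ape::write.tree(simulate_tree(8, 1, seed = 1))
  expect_identical(a, b)                        # seed determinism

  tr50 <- simulate_tree(50, 1, seed = 3)
  expect_length(tr50$tip.label, 50)
  expect_true(all(tr50$edge.length > 0))
  tips <- ape::node.depth.edgelength(tr50)[1:50]
  expect_lt(diff(range(tips)), 1e-8)            # ultrametric
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(mu_extein = 0.1, mu_intein = 0.05), "mu_intein")
  expect_error(sim_config(large_len = 200, mini_len = 150), "large_len")
  expect_error(sim_config(missing_frac = 1), "missing_frac")
  expect_error(sim_config(invasion_rate = -1), "rates")
})

test_that("a root-borne intein with no losses or transfers fixes in all leaves", {
  cfg <- sim_config(n_taxa = 10, n_alleles = 2, invasion_rate = 0,
                    transfer_rate = 0, hen_loss_rate = 0, deletion_rate = 0,
                    missing_frac = 0, seed = 11)
  tr <- simulate_tree(10, 1, seed = 11)
  truth <- simulate_homing(tr, cfg, root_states = c("L", "A"),
                           evolve_sequences = FALSE)
  expect_true(all(truth$full_states[, 1] == "LARGE"))
  expect_true(all(truth$full_states[, 2] == "ABSENT"))
  chr <- setNames(as.integer(truth$full_states[, 1] == "LARGE"), tr$tip.label)
  expect_equal(fitch_events(tr, chr), 0)        # uniform presence: no change
})

test_that("overwhelming loss rates drive every allele to absence", {
  cfg <- sim_config(n_taxa = 8, n_alleles = 3, invasion_rate = 0,
                    transfer_rate = 0, hen_loss_rate = 300, deletion_rate = 300,
                    missing_frac = 0, seed = 5)
  tr <- simulate_tree(8, 1, seed = 5)
  truth <- simulate_homing(tr, cfg, root_states = c("L", "L", "M"),
                           evolve_sequences = FALSE)
  expect_true(all(truth$full_states == "ABSENT"))
})

test_that("the event log respects the homing state machine", {
  cfg <- sim_config(n_taxa = 14, n_alleles = 4, seed = 9, missing_frac = 0)
  tr <- simulate_tree(14, 1, seed = 9)
  truth <- simulate_homing(tr, cfg, evolve_sequences = FALSE)
  ev <- truth$events
  expect_true(!is.unsorted(ev$time))
  expect_true(all(is.na(ev$donor) | ev$event == "transfer"))
  expect_true(all(!is.na(ev$donor[ev$event == "transfer"])))

  # every MINI leaf has a LARGE episode (invasion or transfer followed by
  # hen_loss) somewhere on its root path
  path_nodes <- function(tip) {
    nodes <- tip
    parent <- setNames(tr$edge[, 1], tr$edge[, 2])
    while (!is.null(p <- parent[as.character(nodes[length(nodes)])]) &&
           !is.na(p)) nodes <- c(nodes, unname(p))
    nodes
  }
  for (a in colnames(truth$full_states)) {
    minis <- which(truth$full_states[, a] == "MINI")
    for (tip in minis) {
      anc <- path_nodes(tip)
      eva <- ev[ev$allele == a & ev$branch %in% anc, ]
      expect_true(any(eva$event %in% c("invasion", "transfer")))
      expect_true(any(eva$event == "hen_loss"))
    }
  }
})

test_that("the mini fraction rises with the HEN-loss rate over replicates", {
  frac <- function(hen) {
    f <- numeric(0)
    for (s in 1:50) {
      cfg <- sim_config(n_taxa = 10, n_alleles = 3, hen_loss_rate = hen,
                        deletion_rate = 0, missing_frac = 0, seed = 300 + s)
      tr <- simulate_tree(10, 1, seed = 300 + s)
      st <- simulate_homing(tr, cfg, evolve_sequences = FALSE)$full_states
      nb <- sum(st %in% c("MINI", "LARGE"))
      if (nb > 0) f <- c(f, sum(st == "MINI") / nb)
    }
    mean(f)
  }
  expect_lt(frac(0.05), frac(0.8))
})

test_that("intein blocks diverge faster than extein blocks", {
  cfg <- sim_config(n_taxa = 8, n_alleles = 1, invasion_rate = 0,
                    transfer_rate = 0, hen_loss_rate = 0, deletion_rate = 0,
                    missing_frac = 0, seed = 21)
  tr <- simulate_tree(8, 1, seed = 21)
  truth <- simulate_homing(tr, cfg, root_states = "L")
  site <- truth$insertion_sites[[1]]
  L <- cfg$large_len
  ident <- function(x, y) {
    vx <- strsplit(x, "")[[1]]; vy <- strsplit(y, "")[[1]]
    mean(vx == vy)
  }
  prot <- truth$proteins[[1]]
  int_id <- ext_id <- numeric(0)
  for (i in 1:7) for (j in (i + 1):8) {
    pi <- prot[[i]]; pj <- prot[[j]]
    int_id <- c(int_id, ident(substr(pi, site + 1, site + L),
                              substr(pj, site + 1, site + L)))
    ext_id <- c(ext_id, ident(substr(pi, 1, site), substr(pj, 1, site)))
  }
  expect_lt(mean(int_id), mean(ext_id))
})

test_that("emitted fixtures round-trip to the identical truth profile", {
  cfg <- sim_config(n_taxa = 4, n_alleles = 2, seed = 31)
  tr <- simulate_tree(4, 1, seed = 31)
  truth <- simulate_homing(tr, cfg)
  out <- withr::local_tempdir()
  files <- emit_fixture(truth, out)
  expect_true(all(file.exists(files)))
  # cardinality: one FASTA per allele + orthologs, 1 newick, 2 TSV
  expect_length(grep("^proteins_", names(files)), 2)

  prof2 <- read_truth_profile(files[["truth_profile"]])
  expect_identical(prof2$states[rownames(truth$profile$states),
                                colnames(truth$profile$states)],
                   truth$profile$states)

  # all-ABSENT genomes carry the ancestral extein length (no insertion)
  st <- truth$profile$states
  for (a in colnames(st)) {
    fa <- read_fasta(files[[paste0("proteins_", a)]])
    absent <- rownames(st)[st[, a] == "ABSENT"]
    expect_true(all(nchar(fa[absent]) == cfg$extein_len))
  }

  # byte stability under the same seed
  truth_b <- simulate_homing(simulate_tree(4, 1, seed = 31), cfg)
  out_b <- withr::local_tempdir()
  files_b <- emit_fixture(truth_b, out_b)
  for (nm in names(files)) {
    expect_identical(readLines(files[[nm]]), readLines(files_b[[nm]]),
                     info = nm)
  }
})
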