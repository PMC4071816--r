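#' Configuration for the homing-cycle simulator
#'
#' Bundles every tunable parameter of the forward simulation, with validation.
#' Rates are per unit branch-length time of the species tree. The intein
#' substitution rate must be at least the extein rate, reflecting the elevated
#' substitution rate of inteins relative to their hosts, and large inteins must
#' exceed mini inteins by at least 100 aa so that the downstream length-gap
#' classifier operates in its intended regime.
#'
#' @param n_taxa number of leaves of the simulated species tree (>= 2).
#' @param birth_rate speciation rate of the pure-birth tree prior.
#' @param mu_extein substitutions/site/unit time for extein (host) positions.
#' @param mu_intein substitutions/site/unit time for intein positions
#'   (must be >= `mu_extein`).
#' @param n_alleles number of intein alleles (distinct host gene + insertion
#'   site combinations) simulated independently.
#' @param invasion_rate per-lineage rate of de novo entry of a large intein
#'   from an external pool. Entry is only possible while the allele is absent
#'   from every live lineage (a single founding invasion; re-entry becomes
#'   possible again after global loss, completing the homing cycle).
#' @param transfer_rate per donor-recipient pair base rate of HEN-mediated
#'   homing into an intein-free site.
#' @param decay_lambda patristic-distance scale of the transfer kernel
#'   `exp(-d / decay_lambda)`; smaller values bias transfer more strongly
#'   toward close relatives.
#' @param hen_loss_rate per-lineage rate of HEN-domain loss (LARGE -> MINI).
#' @param deletion_rate per-lineage rate of precise deletion (MINI -> ABSENT).
#' @param large_len,mini_len amino-acid lengths of large and mini inteins;
#'   `large_len - mini_len >= 100`.
#' @param extein_len amino-acid length of each host protein (without intein).
#' @param missing_frac fraction of genome x allele cells masked as MISSING in
#'   the emitted truth (unsequenced/unfound host genes); in `[0, 1)`.
#' @param n_slices number of discrete time slices used to draw contemporaneous
#'   transfer events (slice width = tree height / `n_slices`).
#' @param seed optional integer seed applied at the start of
#'   [simulate_homing()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_taxa = 8, seed = 1)
sim_config <- function(n_taxa = 12L, birth_rate = 1, mu_extein = 0.02,
                       mu_intein = 0.08, n_alleles = 4L, invasion_rate = 1.5,
                       transfer_rate = 2, decay_lambda = 1,
                       hen_loss_rate = 0.3, deletion_rate = 0.1,
                       large_len = 450L, mini_len = 160L, extein_len = 400L,
                       missing_frac = 0.05, n_slices = 100L, seed = NULL) {
  rates <- c(birth_rate = birth_rate, mu_extein = mu_extein,
             mu_intein = mu_intein, invasion_rate = invasion_rate,
             transfer_rate = transfer_rate, hen_loss_rate = hen_loss_rate,
             deletion_rate = deletion_rate, decay_lambda = decay_lambda)
  if (any(!is.finite(rates)) || any(rates < 0))
    stopf("all rates must be finite and >= 0")
  if (mu_intein < mu_extein)
    stopf("mu_intein (%g) must be >= mu_extein (%g)", mu_intein, mu_extein)
  if (n_taxa < 2) stopf("n_taxa must be >= 2")
  if (n_alleles < 1) stopf("n_alleles must be >= 1")
  if (large_len - mini_len < 100)
    stopf("large_len - mini_len must be >= 100 (got %d)", large_len - mini_len)
  if (mini_len < 10) stopf("mini_len must be >= 10")
  if (extein_len < 40) stopf("extein_len must be >= 40")
  if (missing_frac < 0 || missing_frac >= 1)
    stopf("missing_frac must be in [0, 1)")
  if (n_slices < 10) stopf("n_slices must be >= 10")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 mu_extein = mu_extein, mu_intein = mu_intein,
                 n_alleles = as.integer(n_alleles),
                 invasion_rate = invasion_rate, transfer_rate = transfer_rate,
                 decay_lambda = decay_lambda, hen_loss_rate = hen_loss_rate,
                 deletion_rate = deletion_rate,
                 large_len = as.integer(large_len),
                 mini_len = as.integer(mini_len),
                 extein_len = as.integer(extein_len),
                 missing_frac = missing_frac,
                 n_slices = as.integer(n_slices), seed = seed),
            class = "sim_config")
}

#' Simulate an ultrametric species tree under a pure-birth process
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer seed (the generator is deterministic given the
#'   seed).
#' @return An ultrametric binary `phylo` tree with leaves labelled
#'   `g001, g002, ...`.
#' @export
#' @examples
#' tr <- simulate_tree(8, 1, seed = 1)
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 2) stopf("n_taxa must be >= 2")
  if (birth_rate <= 0) stopf("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("g%03d", seq_len(n_taxa))
  tr
}

# Internal: one lineage's full state: per-allele symbiotic state plus
# integer-coded extein and intein sequences.
new_lineage <- function(n_alleles, exteins, states = NULL, inteins = NULL) {
  list(state = if (is.null(states)) rep("A", n_alleles) else states,
       ext = exteins,
       int = if (is.null(inteins)) vector("list", n_alleles) else inteins)
}

#' Forward-simulate the intein homing cycle on a species tree
#'
#' Walks the tree from root to tips in discrete time slices. On each lineage
#' and for each allele independently: an absent site can be invaded de novo by
#' a large intein from an external pool (only while the allele is globally
#' absent, i.e. a single founding invasion per episode); a large intein can
#' lose its HEN domain and become a mini intein; a mini intein can be precisely
#' deleted. Between contemporaneous lineages, a large intein homes into an
#' intein-free site at rate `transfer_rate * exp(-d / decay_lambda)` where `d`
#' is the donor-recipient patristic distance at event time. Mini inteins and
#' absent sites never donate; occupied sites are never re-invaded.
#'
#' Sequences (optional) evolve by uniform amino-acid replacement at
#' `mu_extein` (extein sites) and `mu_intein` (intein sites). The splicing
#' motif residues (intein residues 1 and the last two) and the +1 extein
#' residue are invariant, modelling purifying selection on splicing function.
#' HEN loss deletes a fixed internal segment of length
#' `large_len - mini_len`, so mini inteins of an allele align to the large
#' inteins with a gap exactly at the HEN region.
#'
#' @param tree a `phylo` species tree with unique leaf labels (typically from
#'   [simulate_tree()]).
#' @param config a [sim_config()] object.
#' @param root_states optional character vector of length `n_alleles` over
#'   `"A"`, `"L"`, `"M"` giving the state at the root (default all absent);
#'   use `"L"` to force a founding invasion on the root.
#' @param evolve_sequences if `FALSE`, skip sequence evolution entirely
#'   (states and event log only; much faster for replicate sweeps).
#' @return An object of class `simulation_truth`: a list with elements
#'   `profile` (an [allele_profile()] with `missing_frac` cells masked),
#'   `full_states` (unmasked state matrix), `masked` (logical matrix),
#'   `proteins` (per-allele named character vectors of host proteins, masked
#'   cells omitted), `coords` (data frame of true 0-based half-open intein
#'   coordinates), `events` (ordered event log), `tree`, `config`,
#'   `ancestral_exteins`, `founders`, `insertion_sites`, `hen_region`,
#'   `plus_one`.
#' @export
#' @examples
#' cfg <- sim_config(n_taxa = 6, n_alleles = 2, seed = 3)
#' tr <- simulate_tree(cfg$n_taxa, cfg$birth_rate, seed = 3)
#' truth <- simulate_homing(tr, cfg)
#' truth$profile
simulate_homing <- function(tree, config, root_states = NULL,
                            evolve_sequences = TRUE) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (anyDuplicated(tree$tip.label)) stopf("tree leaves must be uniquely labelled")
  if (!is.null(config$seed)) set.seed(config$seed)

  nt <- length(tree$tip.label)
  na <- config$n_alleles
  allele_ids <- sprintf("allele_%02d", seq_len(na))
  edge <- tree$edge
  nedge <- nrow(edge)
  nnode <- nt + tree$Nnode
  root <- nt + 1L
  depth <- ape::node.depth.edgelength(tree)
  H <- max(depth[seq_len(nt)])
  dt <- H / config$n_slices
  mrca_full <- ape::mrca(tree, full = TRUE)
  parent_of <- integer(nnode)
  parent_of[edge[, 2]] <- edge[, 1]

  if (is.null(root_states)) root_states <- rep("A", na)
  stopifnot(length(root_states) == na, all(root_states %in% c("A", "L", "M")))

  L <- config$large_len
  hen_len <- L - config$mini_len
  # HEN segment centred inside the intein, clear of the terminal motifs
  hen_from <- max(3L, as.integer(floor((L - hen_len) / 2)))
  hen_to <- hen_from + hen_len - 1L
  stopifnot(hen_to <= L - 2L)
  site <- as.integer(floor(config$extein_len / 2))  # 0-based insertion offset

  # Ancestral exteins and founder (external-pool) inteins, one per allele.
  plus_one <- character(na)
  anc_ext <- vector("list", na)
  founders <- vector("list", na)
  for (a in seq_len(na)) {
    e <- sample.int(20L, config$extein_len, replace = TRUE)
    p1 <- sample(c("C", "S", "T"), 1L)
    e[site + 1L] <- match(p1, AA_ALPHABET20)  # +1 extein residue (0-based `site`)
    plus_one[a] <- p1
    f <- sample.int(20L, L, replace = TRUE)
    f[1L] <- match(sample(c("C", "S", "A"), 1L), AA_ALPHABET20)
    f[L - 1L] <- match("H", AA_ALPHABET20)
    f[L] <- match(sample(c("N", "Q"), 1L), AA_ALPHABET20)
    anc_ext[[a]] <- e
    founders[[a]] <- f
  }

  p_inv <- 1 - exp(-config$invasion_rate * dt)
  p_hl <- 1 - exp(-config$hen_loss_rate * dt)
  p_del <- 1 - exp(-config$deletion_rate * dt)
  pm_e <- 1 - exp(-config$mu_extein * dt)
  pm_i <- 1 - exp(-config$mu_intein * dt)

  mutate_seq <- function(s, p, protect) {
    idx <- which(runif(length(s)) < p)
    idx <- setdiff(idx, protect)
    if (length(idx))
      s[idx] <- ((s[idx] - 1L + sample.int(19L, length(idx), replace = TRUE)) %% 20L) + 1L
    s
  }

  node_state <- vector("list", nnode)
  root_int <- vector("list", na)
  for (a in seq_len(na)) {
    if (root_states[a] == "L") root_int[[a]] <- founders[[a]]
    if (root_states[a] == "M") root_int[[a]] <- founders[[a]][-(hen_from:hen_to)]
  }
  node_state[[root]] <- new_lineage(na, anc_ext, root_states, root_int)

  # resolve the lineage state at a node, climbing through branches too short
  # to contain a slice midpoint (they experience no events)
  get_node_lineage <- function(p) {
    if (!is.null(node_state[[p]])) return(node_state[[p]])
    s <- get_node_lineage(parent_of[p])
    node_state[[p]] <<- s
    s
  }

  cur <- vector("list", nedge)
  active_prev <- rep(FALSE, nedge)
  t_par <- depth[edge[, 1]]
  t_chi <- depth[edge[, 2]]
  ev <- list()  # event accumulator
  add_event <- function(time, branch, allele, event, donor = NA_integer_) {
    ev[[length(ev) + 1L]] <<- list(time = time, branch = branch,
                                   allele = allele, event = event,
                                   donor = donor)
  }

  for (k in seq_len(config$n_slices)) {
    tmid <- (k - 0.5) * dt
    act <- t_par <= tmid & tmid < t_chi
    for (e in which(active_prev & !act)) {
      node_state[[edge[e, 2]]] <- cur[[e]]
      cur[e] <- list(NULL)
    }
    for (e in which(act & !active_prev)) cur[[e]] <- get_node_lineage(edge[e, 1])
    ae <- which(act)
    if (!length(ae)) { active_prev <- act; next }

    for (a in seq_len(na)) {
      st <- vapply(ae, function(e) cur[[e]]$state[a], "")
      # de novo invasion from the external pool, gated on global absence
      if (config$invasion_rate > 0 && !any(st != "A")) {
        cand <- ae[runif(length(ae)) < p_inv]
        if (length(cand)) {
          e <- cand[sample.int(length(cand), 1L)]
          cur[[e]]$state[a] <- "L"
          cur[[e]]$int[[a]] <- founders[[a]]
          add_event(tmid, edge[e, 2], allele_ids[a], "invasion")
          st[match(e, ae)] <- "L"
        }
      }
      # HEN loss and precise deletion (independent per lineage)
      for (i in seq_along(ae)) {
        e <- ae[i]
        if (st[i] == "L" && config$hen_loss_rate > 0 && runif(1) < p_hl) {
          cur[[e]]$state[a] <- "M"
          cur[[e]]$int[[a]] <- cur[[e]]$int[[a]][-(hen_from:hen_to)]
          add_event(tmid, edge[e, 2], allele_ids[a], "hen_loss")
        } else if (st[i] == "M" && config$deletion_rate > 0 && runif(1) < p_del) {
          cur[[e]]$state[a] <- "A"
          cur[[e]]$int[a] <- list(NULL)
          add_event(tmid, edge[e, 2], allele_ids[a], "deletion")
        }
      }
      # homing transfers: LARGE donors into ABSENT recipients, distance-biased
      if (config$transfer_rate > 0) {
        don <- ae[vapply(ae, function(e) cur[[e]]$state[a], "") == "L"]
        rec <- ae[vapply(ae, function(e) cur[[e]]$state[a], "") == "A"]
        if (length(don) && length(rec)) {
          for (r in rec) {
            d <- 2 * (tmid - depth[mrca_full[cbind(edge[don, 2], edge[r, 2])]])
            w <- config$transfer_rate * exp(-d / config$decay_lambda)
            haz <- sum(w)
            if (haz > 0 && runif(1) < 1 - exp(-haz * dt)) {
              dn <- don[sample.int(length(don), 1L, prob = w)]
              cur[[r]]$state[a] <- "L"
              cur[[r]]$int[[a]] <- cur[[dn]]$int[[a]]
              add_event(tmid, edge[r, 2], allele_ids[a], "transfer",
                        donor = edge[dn, 2])
            }
          }
        }
      }
    }

    if (evolve_sequences) {
      for (e in ae) {
        for (a in seq_len(na)) {
          cur[[e]]$ext[[a]] <- mutate_seq(cur[[e]]$ext[[a]], pm_e, site + 1L)
          iv <- cur[[e]]$int[[a]]
          if (!is.null(iv)) {
            n <- length(iv)
            cur[[e]]$int[[a]] <- mutate_seq(iv, pm_i, c(1L, n - 1L, n))
          }
        }
      }
    }
    active_prev <- act
  }
  for (e in which(active_prev)) node_state[[edge[e, 2]]] <- cur[[e]]
  for (tip in seq_len(nt)) if (is.null(node_state[[tip]])) get_node_lineage(tip)

  # assemble truth
  smap <- c(A = "ABSENT", L = "LARGE", M = "MINI")
  states <- matrix("ABSENT", nt, na,
                   dimnames = list(tree$tip.label, allele_ids))
  lens <- matrix(NA_integer_, nt, na,
                 dimnames = list(tree$tip.label, allele_ids))
  proteins <- setNames(vector("list", na), allele_ids)
  coords <- list()
  for (a in seq_len(na)) {
    pr <- character(nt)
    for (tip in seq_len(nt)) {
      lin <- node_state[[tip]]
      states[tip, a] <- smap[[lin$state[a]]]
      ext <- lin$ext[[a]]
      if (lin$state[a] == "A") {
        pr[tip] <- code_to_aa(ext)
      } else {
        iv <- lin$int[[a]]
        lens[tip, a] <- length(iv)
        pr[tip] <- code_to_aa(c(ext[seq_len(site)], iv,
                                ext[(site + 1L):length(ext)]))
        coords[[length(coords) + 1L]] <-
          list(genome = tree$tip.label[tip], allele = allele_ids[a],
               start = site, end = site + length(iv))
      }
    }
    proteins[[a]] <- setNames(pr, tree$tip.label)
  }

  masked <- matrix(FALSE, nt, na, dimnames = dimnames(states))
  n_mask <- as.integer(round(config$missing_frac * nt * na))
  if (n_mask > 0) masked[sample.int(nt * na, n_mask)] <- TRUE
  full_states <- states
  states[masked] <- "MISSING"
  lens[masked] <- NA_integer_
  for (a in seq_len(na))
    proteins[[a]] <- proteins[[a]][!masked[, a]]

  events <- if (length(ev)) {
    data.frame(time = vapply(ev, `[[`, 0, "time"),
               branch = vapply(ev, `[[`, 0L, "branch"),
               allele = vapply(ev, `[[`, "", "allele"),
               event = vapply(ev, `[[`, "", "event"),
               donor = vapply(ev, `[[`, 0L, "donor"))
  } else {
    data.frame(time = numeric(0), branch = integer(0), allele = character(0),
               event = character(0), donor = integer(0))
  }

  coords <- if (length(coords)) {
    data.frame(genome = vapply(coords, `[[`, "", "genome"),
               allele = vapply(coords, `[[`, "", "allele"),
               start = vapply(coords, `[[`, 0L, "start"),
               end = vapply(coords, `[[`, 0L, "end"))
  } else {
    data.frame(genome = character(0), allele = character(0),
               start = integer(0), end = integer(0))
  }

  structure(list(
    profile = allele_profile(states, lens),
    full_states = full_states, masked = masked,
    proteins = if (evolve_sequences) proteins else NULL,
    coords = coords, events = events, tree = tree, config = config,
    ancestral_exteins = setNames(vapply(anc_ext, code_to_aa, ""), allele_ids),
    founders = setNames(vapply(founders, code_to_aa, ""), allele_ids),
    insertion_sites = setNames(rep(site, na), allele_ids),
    hen_region = c(from = hen_from, to = hen_to),
    plus_one = setNames(plus_one, allele_ids)
  ), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d genomes x %d alleles, %d events\n",
              nrow(x$full_states), ncol(x$full_states), nrow(x$events)))
  tab <- table(factor(x$profile$states,
                      levels = c("ABSENT", "MINI", "LARGE", "MISSING")))
  cat("  cell states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated data set to disk as a plain-text fixture
#'
#' Emits, under `out_dir`: one protein FASTA per allele (masked genomes
#' omitted), the intein-free ancestral exteins as reference orthologs, the
#' species tree in newick, the truth profile as a long TSV (`genome`, `allele`,
#' `state`, `start`, `end`; coordinates 0-based half-open) and the event log as
#' TSV. Output is byte-stable given the simulation seed.
#'
#' @param truth a `simulation_truth` from [simulate_homing()] run with
#'   `evolve_sequences = TRUE`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
emit_fixture <- function(truth, out_dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(truth$proteins))
    stopf("truth has no sequences; rerun simulate_homing() with evolve_sequences = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  files <- character(0)
  for (a in names(truth$proteins)) {
    f <- file.path(out_dir, paste0("proteins_", a, ".fasta"))
    write_fasta(truth$proteins[[a]], f)
    files[paste0("proteins_", a)] <- f
  }
  f <- file.path(out_dir, "reference_exteins.fasta")
  write_fasta(truth$ancestral_exteins, f)
  files["reference_exteins"] <- f
  f <- file.path(out_dir, "species_tree.nwk")
  write_newick(truth$tree, f)
  files["tree"] <- f

  st <- truth$profile$states
  long <- data.frame(
    genome = rep(rownames(st), times = ncol(st)),
    allele = rep(colnames(st), each = nrow(st)),
    state = c(unname(st)),
    start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
  key <- paste(long$genome, long$allele)
  ck <- paste(truth$coords$genome, truth$coords$allele)
  m <- match(key, ck)
  keep_coord <- !is.na(m) & long$state %in% c("MINI", "LARGE")
  long$start[keep_coord] <- truth$coords$start[m[keep_coord]]
  long$end[keep_coord] <- truth$coords$end[m[keep_coord]]
  long <- long[order(long$genome, long$allele), , drop = FALSE]
  f <- file.path(out_dir, "truth_profile.tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  files["truth_profile"] <- f

  f <- file.path(out_dir, "events.tsv")
  write.table(truth$events, f, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  files["events"] <- f
  invisible(files)
}

#' Read back a truth-profile TSV written by [emit_fixture()]
#'
#' @param path path to `truth_profile.tsv`.
#' @return An [allele_profile()].
#' @export
read_truth_profile <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "allele", "state", "start", "end")
  if (!all(need %in% names(d)))
    stopf("truth profile must have columns %s", paste(need, collapse = ", "))
  genomes <- unique(d$genome)
  alleles <- unique(d$allele)
  st <- matrix("MISSING", length(genomes), length(alleles),
               dimnames = list(genomes, alleles))
  ln <- matrix(NA_integer_, length(genomes), length(alleles),
               dimnames = list(genomes, alleles))
  st[cbind(d$genome, d$allele)] <- d$state
  has_len <- d$state %in% c("MINI", "LARGE")
  ln[cbind(d$genome[has_len], d$allele[has_len])] <-
    as.integer(d$end[has_len] - d$start[has_len])
  allele_profile(st, ln)
}
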