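# Seeded simulator of autopolyploid populations with full-sib families and
# multi-marker haploblocks (no recombination within blocks), plus
# truth-based scoring of haplotyping results.

#' Simulation configuration
#'
#' Describes a population design: founder pools, full-sib families, and
#' per-block marker counts. Founders (parents and unrelated individuals)
#' draw their haplotypes from per-population pools of distinct haplotypes
#' with geometrically decaying frequencies; optional clusters of related
#' founders share a restricted subset of the pool.
#'
#' @param ploidy Even ploidy level (default 4).
#' @param n_blocks Number of haploblocks (default 60).
#' @param markers_per_block Marker counts cycled over blocks (default
#'   `3:7`, i.e. equally many blocks of each size).
#' @param n_founder_haps Target number of distinct founder haplotypes per
#'   block and population (capped at `2^nmrk`; default 16).
#' @param pool_decay Geometric decay of founder haplotype frequencies
#'   (default 0.75; smaller values concentrate the pool and reduce
#'   SNP heterozygosity).
#' @param cluster_frac Fraction of the population pool available to each
#'   founder cluster (default 0.6).
#' @param parents Tibble with columns `indiv`, `population` (integer) and
#'   optional `cluster` (integer, `NA` = no cluster).
#' @param families Tibble with columns `family`, `parent1`, `parent2`,
#'   `n_offspring`.
#' @param n_unrelated Integer vector: unrelated individuals to draw per
#'   population (default none).
#' @param alpha Double-reduction frequency used in meiosis (default 0.025).
#' @param epsilon_sim Probability of a +/-1 dosage-scoring error applied to
#'   the emitted dosages (default 0: error-free, as in the validation
#'   designs).
#' @param missing_rate Probability that an emitted dosage is missing
#'   (default 0).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ploidy = 4, n_blocks = 60, markers_per_block = 3:7,
                       n_founder_haps = 16, pool_decay = 0.75,
                       cluster_frac = 0.6, parents, families,
                       n_unrelated = integer(), alpha = 0.025,
                       epsilon_sim = 0, missing_rate = 0, seed = 1L) {
  ploidy <- check_ploidy(ploidy)
  stopifnot(all(c("indiv", "population") %in% names(parents)),
            all(c("family", "parent1", "parent2", "n_offspring") %in%
                  names(families)),
            all(families$parent1 %in% parents$indiv),
            all(families$parent2 %in% parents$indiv),
            alpha >= 0, alpha < 1, epsilon_sim >= 0, epsilon_sim < 1,
            missing_rate >= 0, missing_rate < 1, n_founder_haps >= 1)
  if (is.null(parents$cluster)) parents$cluster <- NA_integer_
  structure(list(ploidy = ploidy, n_blocks = as.integer(n_blocks),
                 markers_per_block = as.integer(markers_per_block),
                 n_founder_haps = as.integer(n_founder_haps),
                 pool_decay = pool_decay, cluster_frac = cluster_frac,
                 parents = tibble::as_tibble(parents),
                 families = tibble::as_tibble(families),
                 n_unrelated = as.integer(n_unrelated),
                 alpha = alpha, epsilon_sim = epsilon_sim,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset: several tetraploid full-sib families sharing one parent
#'
#' A panel of full-sib families that all share one common parent, with the
#' parents structured into clusters of related founders from a single
#' population -- the classic multi-family validation design (by default 9
#' families of 50, 10 parents in 3 clusters, 60 blocks of 3-7 markers,
#' error-free and complete dosages).
#'
#' @param n_families,family_size Family structure.
#' @param n_clusters Number of related-founder clusters among the parents.
#' @param ... Passed on to [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_design_shared_parent <- function(n_families = 9, family_size = 50,
                                     n_clusters = 3, seed = 1L, ...) {
  n_par <- n_families + 1L
  ids <- sprintf("P%02d", seq_len(n_par))
  cluster <- sort(rep(seq_len(n_clusters), length.out = n_par))
  parents <- tibble::tibble(indiv = ids, population = 1L, cluster = cluster)
  families <- tibble::tibble(
    family = sprintf("F%d", seq_len(n_families)),
    parent1 = ids[1L],
    parent2 = ids[-1L],
    n_offspring = as.integer(family_size))
  sim_config(parents = parents, families = families, seed = seed, ...)
}

#' Preset: two full-sib families plus unrelated material from two sources
#'
#' Two full-sib families sharing one parent, with the three parents drawn
#' from two distinct random-mating populations, plus a group of unrelated
#' individuals from each population (by default 2 x 50 offspring and
#' 2 x 50 unrelated, 60 blocks of 3-7 markers).
#'
#' @param family_size Offspring per family.
#' @param n_unrelated Unrelated individuals per population.
#' @param ... Passed on to [sim_config()].
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_design_two_populations <- function(family_size = 50, n_unrelated = 50,
                                       seed = 1L, ...) {
  parents <- tibble::tibble(indiv = c("P01", "P02", "P03"),
                            population = c(1L, 1L, 2L),
                            cluster = NA_integer_)
  families <- tibble::tibble(family = c("F1", "F2"),
                             parent1 = c("P01", "P01"),
                             parent2 = c("P02", "P03"),
                             n_offspring = as.integer(family_size))
  sim_config(parents = parents, families = families,
             n_unrelated = rep(as.integer(n_unrelated), 2L),
             seed = seed, ...)
}

# founder haplotype pool for one block and population: distinct codes with
# geometrically decaying frequencies
founder_pool <- function(nmrk, cfg) {
  nhap <- 2L^nmrk
  m <- min(cfg$n_founder_haps, nhap)
  codes <- sample(0:(nhap - 1L), m)
  w <- cfg$pool_decay^(seq_len(m) - 1L)
  list(codes = codes, w = w / sum(w))
}

draw_founder <- function(pool, sub, ploidy) {
  idx <- if (is.null(sub)) seq_along(pool$codes) else sub
  sort(sample(pool$codes[idx], ploidy, replace = TRUE,
              prob = pool$w[idx] / sum(pool$w[idx])))
}

#' Simulate founder haplotype combinations
#'
#' Draws the founder (parent and unrelated) haplotype combinations for
#' every block of a design; part of [simulate_population()] but exposed
#' for inspection of the founder structure.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `block`, `indiv`, and list-column `ghap`.
#' @export
simulate_founders <- function(config) {
  sim <- simulate_population(config)
  unrel <- unlist(lapply(seq_along(config$n_unrelated), function(p)
    sprintf("U%d_%02d", p, seq_len(config$n_unrelated[p]))))
  founders <- c(config$parents$indiv, unrel)
  sim$truth[sim$truth$indiv %in% founders, ]
}

# one meiosis: sample a gamete from a parental haplotype combination
sample_gamete <- function(ghap, alpha) {
  p <- length(ghap)
  k <- p %/% 2L
  if (k >= 2L && stats::runif(1L) < alpha) {
    i <- sample.int(p, 1L)
    rest <- if (k > 2L) sample(ghap[-i], k - 2L) else integer(0)
    sort(c(ghap[i], ghap[i], rest))
  } else {
    sort(ghap[sample.int(p, k)])
  }
}

#' Simulate a full-sib cross
#'
#' Each offspring receives one gamete from each parent, sampled under the
#' polysomic gamete model with double-reduction frequency `alpha`.
#'
#' @param p1,p2 Parental haplotype combinations (sorted integer vectors).
#' @param n Number of offspring.
#' @param alpha Double-reduction frequency.
#' @param seed Optional seed.
#' @return `ploidy x n` integer matrix of offspring combinations.
#' @export
simulate_cross <- function(p1, p2, n, alpha = 0.025, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(p1) == length(p2))
  vapply(seq_len(n), function(i) {
    sort(c(sample_gamete(p1, alpha), sample_gamete(p2, alpha)))
  }, integer(length(p1)))
}

#' Simulate a polyploid population with haploblocks
#'
#' Generates founder haplotype combinations from per-population pools,
#' crosses the full-sib families (one gamete per parent per offspring, no
#' recombination within blocks), and emits the SNP dosage matrix with
#' optional dosage errors and missing data, together with the true
#' haplotype compositions.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_population` with `dosages` (matrix),
#'   `blocks` (named list), `families` (tibble with `offspring`
#'   list-column, ready for [infer_haplotypes()]), `truth` (tibble:
#'   block, indiv, `ghap` list-column), and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ploidy <- config$ploidy
  sizes <- sort(rep(config$markers_per_block,
                    length.out = config$n_blocks))
  bnames <- sprintf("block%03d", seq_len(config$n_blocks))

  fam <- config$families
  off_ids <- lapply(seq_len(nrow(fam)), function(i)
    sprintf("%s_%02d", fam$family[i], seq_len(fam$n_offspring[i])))
  unrel_ids <- lapply(seq_along(config$n_unrelated), function(p)
    sprintf("U%d_%02d", p, seq_len(config$n_unrelated[p])))
  all_ids <- c(config$parents$indiv, unlist(off_ids), unlist(unrel_ids))

  blocks <- list()
  dos_rows <- list()
  truth_rows <- list()
  for (bi in seq_len(config$n_blocks)) {
    nmrk <- sizes[bi]
    mk <- sprintf("%s_m%d", bnames[bi], seq_len(nmrk))
    blocks[[bnames[bi]]] <- mk

    pops <- sort(unique(config$parents$population))
    pools <- lapply(pops, function(p) founder_pool(nmrk, config))
    names(pools) <- as.character(pops)
    # cluster-restricted index subsets of each population pool
    subsets <- list()
    for (ci in unique(stats::na.omit(config$parents$cluster))) {
      pop <- config$parents$population[match(ci, config$parents$cluster)]
      pool <- pools[[as.character(pop)]]
      msub <- max(2L, ceiling(config$cluster_frac * length(pool$codes)))
      subsets[[as.character(ci)]] <- sort(sample(seq_along(pool$codes), msub))
    }

    ghap <- list()
    for (i in seq_len(nrow(config$parents))) {
      pid <- config$parents$indiv[i]
      pool <- pools[[as.character(config$parents$population[i])]]
      sub <- if (!is.na(config$parents$cluster[i]))
        subsets[[as.character(config$parents$cluster[i])]] else NULL
      ghap[[pid]] <- draw_founder(pool, sub, ploidy)
    }
    for (p in seq_along(config$n_unrelated)) {
      pool <- pools[[as.character(pops[min(p, length(pops))])]]
      for (id in unrel_ids[[p]]) ghap[[id]] <- draw_founder(pool, NULL, ploidy)
    }
    for (i in seq_len(nrow(fam))) {
      g1 <- ghap[[fam$parent1[i]]]
      g2 <- ghap[[fam$parent2[i]]]
      for (id in off_ids[[i]]) {
        ghap[[id]] <- sort(c(sample_gamete(g1, config$alpha),
                             sample_gamete(g2, config$alpha)))
      }
    }

    gm <- vapply(all_ids, function(id) mrkdos_of_hapcomb(ghap[[id]], nmrk),
                 integer(nmrk))
    gm <- matrix(gm, nrow = nmrk, dimnames = list(mk, all_ids))
    if (config$epsilon_sim > 0) {
      err <- matrix(stats::runif(length(gm)) < config$epsilon_sim,
                    nrow = nmrk)
      dir <- matrix(sample(c(-1L, 1L), length(gm), replace = TRUE),
                    nrow = nmrk)
      shifted <- gm + dir
      shifted[shifted < 0L] <- 1L
      shifted[shifted > ploidy] <- ploidy - 1L
      gm[err] <- shifted[err]
    }
    if (config$missing_rate > 0) {
      gm[matrix(stats::runif(length(gm)) < config$missing_rate,
                nrow = nmrk)] <- NA_integer_
    }
    dos_rows[[bi]] <- gm
    truth_rows[[bi]] <- tibble::tibble(block = bnames[bi], indiv = all_ids,
                                       ghap = unname(ghap[all_ids]))
  }

  families_out <- tibble::tibble(family = fam$family, parent1 = fam$parent1,
                                 parent2 = fam$parent2, offspring = off_ids)
  structure(list(dosages = do.call(rbind, dos_rows), blocks = blocks,
                 families = families_out,
                 truth = dplyr::bind_rows(truth_rows), config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> ploidy %d: %d individuals, %d blocks (%d markers)\n",
              x$config$ploidy, ncol(x$dosages), length(x$blocks),
              nrow(x$dosages)))
  invisible(x)
}

#' Pedigree implied by a simulated population
#'
#' @param sim A `sim_population`.
#' @return Tibble (indiv, parent1, parent2) covering the offspring.
#' @export
sim_pedigree <- function(sim) {
  fam <- sim$families
  dplyr::bind_rows(lapply(seq_len(nrow(fam)), function(i)
    tibble::tibble(indiv = fam$offspring[[i]], parent1 = fam$parent1[i],
                   parent2 = fam$parent2[i])))
}

#' Score haplotyping results against simulated truth
#'
#' An assignment is correct when it equals the true haplotype combination
#' as a multiset.
#'
#' @param result A `hap_result`.
#' @param truth Truth tibble from [simulate_population()] (`block`,
#'   `indiv`, `ghap`).
#' @return Object of class `hap_score`: list with `by_block` (per-block
#'   counts and percentages, numbers of inferred and true haplotypes) and
#'   `overall` (means over blocks and totals).
#' @export
score_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "hap_result"))
  asn <- result$assignments
  rows <- list()
  for (b in unique(asn$block)) {
    sub <- asn[asn$block == b, ]
    tr <- truth[truth$block == b, ]
    tmap <- stats::setNames(tr$ghap, tr$indiv)
    common <- intersect(sub$indiv, tr$indiv)
    sub <- sub[match(common, sub$indiv), ]
    hap <- sub$assigned
    correct <- vapply(seq_len(nrow(sub)), function(i) {
      hap[i] && identical(as.integer(sort(sub$ghap[[i]])),
                          as.integer(sort(tmap[[sub$indiv[i]]])))
    }, logical(1L))
    rows[[b]] <- tibble::tibble(
      block = b, n = length(common), n_haplotyped = sum(hap),
      n_correct = sum(correct),
      pct_haplotyped = 100 * mean(hap),
      pct_correct = if (sum(hap)) 100 * sum(correct) / sum(hap) else NA_real_,
      n_hap_inferred = length(unique(unlist(sub$ghap[hap]))),
      n_hap_true = length(unique(unlist(tmap[common]))))
  }
  by_block <- dplyr::bind_rows(rows)
  overall <- tibble::tibble(
    n_blocks = nrow(by_block),
    mean_pct_haplotyped = mean(by_block$pct_haplotyped),
    mean_pct_correct = mean(by_block$pct_correct, na.rm = TRUE),
    mean_n_hap_inferred = mean(by_block$n_hap_inferred),
    mean_n_hap_true = mean(by_block$n_hap_true),
    total_correct = sum(by_block$n_correct),
    total_incorrect = sum(by_block$n_haplotyped - by_block$n_correct),
    total_not_haplotyped = sum(by_block$n - by_block$n_haplotyped))
  structure(list(by_block = by_block, overall = overall),
            class = "hap_score")
}

#' @export
print.hap_score <- function(x, ...) {
  cat("<hap_score>\n")
  print(x$overall)
  invisible(x)
}
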