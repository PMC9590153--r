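# Stage 2: haplotyping of full-sib families by scoring candidate parental
# haplotype combinations against the observed offspring dosage segregation.

# ---- gamete model -----------------------------------------------------------

# internal gamete support of one parental haplotype combination.
# Normal meiosis: a gamete is a uniform random subset of ploidy/2 of the
# ploidy homologs. Double reduction (frequency alpha): one uniformly chosen
# homolog is duplicated and the remaining gamete slots are filled by a
# uniform subset of the other homologs (none remain for tetraploids, one of
# the other five for hexaploids). Diploids have single-homolog gametes, so
# alpha is ignored.
gamete_support_int <- function(ghap, alpha) {
  p <- length(ghap)
  k <- p %/% 2L
  pos <- utils::combn(p, k)
  gam <- matrix(ghap[pos], nrow = k)
  if (k > 1L) gam <- apply(gam, 2L, sort)
  if (!is.matrix(gam)) gam <- matrix(gam, nrow = k)
  a <- if (k >= 2L) alpha else 0
  pr <- rep((1 - a) / ncol(gam), ncol(gam))
  if (a > 0) {
    if (k == 2L) {
      dr <- vapply(seq_len(p), function(i) rep(ghap[i], 2L), integer(2L))
      pr_dr <- rep(a / p, p)
    } else if (k == 3L) {
      pairs <- expand.grid(i = seq_len(p), j = seq_len(p))
      pairs <- pairs[pairs$i != pairs$j, ]
      dr <- apply(pairs, 1L, function(ij) {
        sort(c(ghap[ij[1L]], ghap[ij[1L]], ghap[ij[2L]]))
      })
      pr_dr <- rep(a / nrow(pairs), nrow(pairs))
    } else {
      stop("double reduction is implemented for ploidy <= 6", call. = FALSE)
    }
    gam <- cbind(gam, dr)
    pr <- c(pr, pr_dr)
  }
  aggregate_columns(gam, pr)
}

# aggregate identical columns (sorted multisets), return lex-ordered support
aggregate_columns <- function(m, pr) {
  key <- apply(m, 2L, paste, collapse = ",")
  agg <- rowsum(pr, key, reorder = FALSE)
  u <- !duplicated(key)
  mu <- m[, u, drop = FALSE]
  ku <- key[u]
  pu <- as.vector(agg[match(ku, rownames(agg)), 1L])
  ord <- do.call(order, lapply(seq_len(nrow(mu)), function(r) mu[r, ]))
  list(g = mu[, ord, drop = FALSE], p = pu[ord])
}

#' Gamete distribution of a parental haplotype combination
#'
#' Distribution over gametes (multisets of `ploidy/2` haplotype codes)
#' produced by polysomic meiosis with double-reduction frequency `alpha`.
#'
#' @param ghap Sorted integer vector of `ploidy` haplotype codes.
#' @param alpha Double-reduction frequency in `[0, 1)`; ignored for
#'   diploids.
#' @return A tibble with list-column `gamete` and numeric `prob`
#'   (summing to 1), in lexicographic gamete order.
#' @examples
#' gamete_distribution(c(0, 0, 1, 1), alpha = 0) # 1/6, 2/3, 1/6
#' @export
gamete_distribution <- function(ghap, alpha = 0.025) {
  ploidy <- check_ploidy(length(ghap))
  stopifnot(alpha >= 0, alpha < 1)
  ghap <- sort(as.integer(ghap))
  s <- gamete_support_int(ghap, alpha)
  tibble::tibble(gamete = lapply(seq_len(ncol(s$g)), function(i) s$g[, i]),
                 prob = s$p)
}

# convolution of two gamete supports into progeny Ghap classes
progeny_support_int <- function(s1, s2) {
  k1 <- ncol(s1$g); k2 <- ncol(s2$g)
  i <- rep(seq_len(k1), times = k2)
  j <- rep(seq_len(k2), each = k1)
  m <- rbind(s1$g[, i, drop = FALSE], s2$g[, j, drop = FALSE])
  m <- apply(m, 2L, sort)
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(s1$g) + nrow(s2$g))
  aggregate_columns(m, s1$p[i] * s2$p[j])
}

#' Expected distribution of progeny haplotype combinations
#'
#' Convolution of the two parental gamete distributions: each offspring
#' receives one gamete from each parent.
#'
#' @param ghap1,ghap2 Parental haplotype combinations (sorted integer
#'   vectors of `ploidy` codes).
#' @inheritParams gamete_distribution
#' @return A tibble with list-column `ghap` and `prob` (summing to 1).
#' @examples
#' progeny_ghap_distribution(c(0, 1), c(0, 0), alpha = 0)
#' @export
progeny_ghap_distribution <- function(ghap1, ghap2, alpha = 0.025) {
  stopifnot(length(ghap1) == length(ghap2))
  s <- progeny_support_int(gamete_support_int(sort(as.integer(ghap1)), alpha),
                           gamete_support_int(sort(as.integer(ghap2)), alpha))
  tibble::tibble(ghap = lapply(seq_len(ncol(s$g)), function(i) s$g[, i]),
                 prob = s$p)
}

# ---- dosage-error model -----------------------------------------------------

# (ploidy+1)^2 transition matrix: T[i+1, j+1] = P(observe dosage j | true i).
# A dosage is read correctly with probability 1-epsilon and as an adjacent
# dosage with probability epsilon, split equally between the two neighbors
# (entirely to the single neighbor at the boundaries).
dosage_error_matrix <- function(ploidy, epsilon) {
  n <- ploidy + 1L
  Tm <- diag(1 - epsilon, n)
  if (epsilon > 0 && n > 1L) {
    for (i in seq_len(n)) {
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= n]
      Tm[i, nb] <- epsilon / length(nb)
    }
  }
  Tm
}

#' Expected marker-dosage segregation of a progeny distribution
#'
#' Pushes a distribution over progeny haplotype combinations through the
#' dosage map and applies the per-marker dosage-error model: independently
#' for each marker, a true dosage `d` is observed as `d` with probability
#' `1 - epsilon` and as an adjacent dosage with probability `epsilon`
#' (split equally between `d - 1` and `d + 1`, entirely to the single
#' neighbor at 0 or ploidy).
#'
#' @param ghap_dist A tibble as returned by [progeny_ghap_distribution()].
#' @param epsilon Dosage-error probability.
#' @param ploidy Even ploidy level.
#' @param nmrk Number of markers in the block.
#' @return A tibble with list-column `gmrk` (integer dosage vectors) and
#'   `prob`, ordered by dosage key.
#' @export
expected_gmrk_distribution <- function(ghap_dist, epsilon, ploidy, nmrk) {
  stopifnot(is.data.frame(ghap_dist), all(c("ghap", "prob") %in% names(ghap_dist)))
  ploidy <- check_ploidy(ploidy)
  gm <- vapply(ghap_dist$ghap, function(h) mrkdos_of_hapcomb(h, nmrk),
               integer(nmrk))
  gm <- matrix(gm, nrow = nmrk)
  key <- gmrk_keys(gm, ploidy)
  agg <- rowsum(ghap_dist$prob, key)
  baseK <- as.integer(rownames(agg))
  baseP <- as.vector(agg[, 1L])
  if (epsilon > 0) {
    Tm <- dosage_error_matrix(ploidy, epsilon)
    pw <- (ploidy + 1)^(seq_len(nmrk) - 1L)
    keys <- baseK
    probs <- baseP
    for (m in seq_len(nmrk)) {
      d <- (keys %/% as.integer(pw[m])) %% (ploidy + 1L)
      pieces <- lapply(0:ploidy, function(v) {
        pr <- probs * Tm[d + 1L, v + 1L]
        ok <- pr > 0
        list(k = keys[ok] + as.integer((v - d[ok]) * pw[m]), p = pr[ok])
      })
      keys <- unlist(lapply(pieces, `[[`, "k"), use.names = FALSE)
      probs <- unlist(lapply(pieces, `[[`, "p"), use.names = FALSE)
      agg <- rowsum(probs, keys)
      keys <- as.integer(rownames(agg))
      probs <- as.vector(agg[, 1L])
    }
    baseK <- keys
    baseP <- probs
  }
  dosM <- gmrk_unkey(baseK, nmrk, ploidy)
  tibble::tibble(gmrk = lapply(seq_along(baseK), function(i) dosM[, i]),
                 prob = baseP)
}

# ---- chi-squared segregation test -------------------------------------------

#' Chi-squared goodness-of-fit of an observed dosage segregation
#'
#' Compares observed per-genotype counts in a full-sib family against an
#' expected marker-dosage distribution. Expected classes with fewer than
#' one expected individual are pooled with all observed-but-unexpected
#' classes into a single category; the Pearson statistic is computed over
#' the remaining categories plus the pooled one, with degrees of freedom
#' `max(categories - 1, 1)`.
#'
#' @param observed A tibble with list-column `gmrk` (integer dosage
#'   vectors) and integer `count`.
#' @param expected A tibble with list-column `gmrk` and `prob`, e.g. from
#'   [expected_gmrk_distribution()].
#' @param n Number of fully genotyped offspring; must equal
#'   `sum(observed$count)`.
#' @return P value in `[0, 1]`.
#' @examples
#' ob <- tibble::tibble(gmrk = list(0L, 1L), count = c(30L, 70L))
#' ex <- tibble::tibble(gmrk = list(0L, 1L), prob = c(0.5, 0.5))
#' fs_segregation_pvalue(ob, ex, 100) # ~6.3e-5
#' @export
fs_segregation_pvalue <- function(observed, expected, n) {
  stopifnot(n >= 1)
  if (!isTRUE(all.equal(sum(observed$count), n))) {
    stop("observed counts must sum to n", call. = FALSE)
  }
  okey <- vapply(observed$gmrk, paste, character(1L), collapse = ",")
  ekey <- vapply(expected$gmrk, paste, character(1L), collapse = ",")
  E <- n * expected$prob
  O_e <- observed$count[match(ekey, okey)]
  O_e[is.na(O_e)] <- 0
  kept <- E >= 1
  stat <- sum((O_e[kept] - E[kept])^2 / E[kept])
  E_pool <- n - sum(E[kept])
  O_pool <- n - sum(O_e[kept])
  ncat <- sum(kept)
  if (E_pool > 1e-12 || O_pool > 0) {
    if (E_pool <= 1e-12) return(0)
    stat <- stat + (O_pool - E_pool)^2 / E_pool
    ncat <- ncat + 1L
  }
  df <- max(ncat - 1L, 1L)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# scoring context: everything about the observed segregation and the
# error model that is constant across candidate parental pairs
seg_context <- function(obs_key, obs_count, n, epsilon, ploidy, nmrk) {
  b <- ploidy + 1L
  pw <- as.numeric(b^(seq_len(nmrk) - 1L))
  list(obs_key = as.numeric(obs_key), obs_count = as.numeric(obs_count),
       n = n, epsilon = epsilon, ploidy = ploidy, nmrk = nmrk, b = b,
       pw = pw, Tm = dosage_error_matrix(ploidy, epsilon),
       # a base class needs at least this probability before a +/-1
       # neighbor of it could reach one expected individual
       heavy_thr = if (epsilon > 0) 1 / (n * epsilon) else Inf)
}

# fast internal scorer working on integer dosage keys. baseK/baseP are the
# error-free expected classes of one candidate parental pair; the error
# model is applied implicitly through the transition matrix, only at the
# classes that can matter (classes whose expected count can reach 1, plus
# all observed classes); everything else is pooled.
seg_pvalue_ctx <- function(ctx, baseK, baseP) {
  candK <- baseK
  if (any(baseP >= ctx$heavy_thr)) {
    heavy <- which(baseP >= ctx$heavy_thr)
    nb <- numeric(0)
    for (m in seq_len(ctx$nmrk)) {
      d <- (baseK[heavy] %/% ctx$pw[m]) %% ctx$b
      nb <- c(nb, baseK[heavy][d < ctx$ploidy] + ctx$pw[m],
              baseK[heavy][d > 0] - ctx$pw[m])
    }
    candK <- c(candK, setdiff(nb, candK))
  }
  extra <- ctx$obs_key[is.na(match(ctx$obs_key, candK))]
  candK <- c(candK, extra)
  tm <- NULL
  for (m in seq_len(ctx$nmrk)) {
    db <- (baseK %/% ctx$pw[m]) %% ctx$b
    dc <- (candK %/% ctx$pw[m]) %% ctx$b
    tm <- if (is.null(tm)) ctx$Tm[db + 1, dc + 1, drop = FALSE]
          else tm * ctx$Tm[db + 1, dc + 1, drop = FALSE]
  }
  pc <- as.vector(baseP %*% tm)
  E <- ctx$n * pc
  O <- numeric(length(candK))
  O[match(ctx$obs_key, candK)] <- ctx$obs_count
  kept <- E >= 1
  stat <- sum((O[kept] - E[kept])^2 / E[kept])
  E_pool <- ctx$n - sum(E[kept])
  O_pool <- ctx$n - sum(O[kept])
  ncat <- sum(kept)
  if (E_pool > 1e-12 || O_pool > 0) {
    if (E_pool <= 1e-12) return(0)
    stat <- stat + (O_pool - E_pool)^2 / E_pool
    ncat <- ncat + 1L
  }
  df <- max(ncat - 1L, 1L)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

seg_pvalue_fast <- function(obs_key, obs_count, baseK, baseP, n,
                            epsilon, ploidy, nmrk) {
  ctx <- seg_context(obs_key, obs_count, n, epsilon, ploidy, nmrk)
  seg_pvalue_ctx(ctx, baseK, baseP)
}

# aggregate probabilities by integer key without factor overhead
key_aggregate <- function(keys, probs) {
  ord <- order(keys)
  ks <- keys[ord]
  ps <- probs[ord]
  len <- length(ks)
  new <- c(TRUE, ks[-1L] != ks[-len])
  ends <- c(which(new) - 1L, len)[-1L]
  cs <- cumsum(ps)
  list(key = ks[new], p = cs[ends] - c(0, cs[ends[-length(ends)]]))
}

# ---- per-parent candidate machinery -----------------------------------------

# memoized per-Ghap gamete info: gamete support + marker-dosage keys of the
# gametes (mixed-radix, base ploidy+1 so parent keys add)
parent_ghap_info <- function(ghap, alpha, nmrk, ploidy, memo = NULL) {
  id <- paste(ghap, collapse = ",")
  if (!is.null(memo) && !is.null(memo[[id]])) return(memo[[id]])
  s <- gamete_support_int(ghap, alpha)
  dosG <- mrkdos_of_hapcomb(s$g, nmrk)
  if (!is.matrix(dosG)) dosG <- matrix(dosG, nrow = nmrk)
  s$key <- gmrk_keys(dosG, ploidy)
  if (!is.null(memo)) memo[[id]] <- s
  s
}

# error-free expected Gmrk classes of a parental pair, via additive keys
pair_base_classes <- function(info1, info2) {
  k1 <- length(info1$p); k2 <- length(info2$p)
  keys <- rep(info1$key, times = k2) + rep(info2$key, each = k1)
  probs <- rep(info1$p, times = k2) * rep(info2$p, each = k1)
  key_aggregate(keys, probs)
}

# progeny Ghap classes of a pair, with class Gmrk keys (for assignment)
pair_ghap_classes <- function(ghap1, ghap2, alpha, nmrk, ploidy) {
  s <- progeny_support_int(gamete_support_int(ghap1, alpha),
                           gamete_support_int(ghap2, alpha))
  dos <- mrkdos_of_hapcomb(s$g, nmrk)
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = nmrk)
  list(ghap = s$g, p = s$p, key = gmrk_keys(dos, ploidy))
}

# ---- solveOneFS -------------------------------------------------------------

demoted <- function(reason) list(status = "demoted", reason = reason)

#' Solve one full-sib family
#'
#' Enumerates candidate parental haplotype-combination pairs and scores
#' each against the observed offspring dosage segregation with the pooled
#' chi-squared test. Pairs built from inventory haplotypes only are tried
#' first; if none is acceptable, all pairs compatible with the parental
#' dosages are scored. The family is demoted to unrelated material when a
#' parent has missing dosages, when the number of pairs exceeds
#' `max_parent_combs`, or when no pair passes the P-value filters
#' (`P >= p_ratio * P_best` and `P > p_min`).
#'
#' @param family List or one-row data frame with elements `family`
#'   (id), `parent1`, `parent2` (individual ids) and `offspring`
#'   (character vector of ids).
#' @param dos Block dosage matrix (markers x individuals, named columns).
#' @param inventory Integer vector of haplotype codes from Stage 1.
#' @param ploidy Even ploidy level.
#' @param params A [hap_params()] list.
#' @param table Optional `hapcomb_table`.
#' @param memo Optional environment memoizing per-Ghap gamete supports
#'   (shared across families with common parents).
#' @return For a solvable family, a list with `status = "candidates"`,
#'   matrices `ghap1`/`ghap2` (columns = surviving candidate pairs),
#'   `p` (their P values), `n_genotyped`, and the observed class counts;
#'   otherwise `status = "demoted"` with a `reason`.
#' @export
solve_one_fs <- function(family, dos, inventory, ploidy,
                         params = hap_params(), table = NULL, memo = NULL) {
  if (is.data.frame(family)) {
    family <- list(family = family$family[1L], parent1 = family$parent1[1L],
                   parent2 = family$parent2[1L],
                   offspring = family$offspring[[1L]])
  }
  ids <- c(family$parent1, family$parent2, family$offspring)
  if (!all(ids %in% colnames(dos))) {
    stop("unknown individual ids in family ", family$family, call. = FALSE)
  }
  nmrk <- nrow(dos)
  gp1 <- dos[, family$parent1]
  gp2 <- dos[, family$parent2]
  if (anyNA(gp1) || anyNA(gp2)) return(demoted("missing_parent_dosages"))
  offd <- dos[, family$offspring, drop = FALSE]
  complete <- colSums(is.na(offd)) == 0L
  n <- sum(complete)
  if (n == 0L) return(demoted("no_acceptable_solution"))
  okeys <- gmrk_keys(offd[, complete, drop = FALSE], ploidy)
  agg <- key_aggregate(okeys, rep(1, n))
  obs_key <- agg$key
  obs_count <- agg$p
  ctx <- seg_context(obs_key, obs_count, n, params$epsilon, ploidy, nmrk)

  selfing <- identical(family$parent1, family$parent2)
  sols1 <- enumerate_hapcombs(gp1, ploidy, table)
  sols2 <- if (selfing) sols1 else enumerate_hapcombs(gp2, ploidy, table)
  if (is.null(memo)) memo <- new.env(parent = emptyenv())

  score_set <- function(c1, c2) {
    n1 <- ncol(c1); n2 <- ncol(c2)
    info1 <- lapply(seq_len(n1), function(i)
      parent_ghap_info(c1[, i], params$alpha, nmrk, ploidy, memo))
    info2 <- if (selfing) info1 else lapply(seq_len(n2), function(j)
      parent_ghap_info(c2[, j], params$alpha, nmrk, ploidy, memo))
    if (selfing) {
      idx <- cbind(seq_len(n1), seq_len(n1))
    } else {
      idx <- cbind(rep(seq_len(n1), each = n2), rep(seq_len(n2), times = n1))
    }
    sm <- score_pairs_cpp(lapply(info1, function(x) as.numeric(x$key)),
                          lapply(info1, function(x) as.numeric(x$p)),
                          lapply(info2, function(x) as.numeric(x$key)),
                          lapply(info2, function(x) as.numeric(x$p)),
                          idx, as.numeric(obs_key), as.numeric(obs_count),
                          n, params$epsilon, ploidy, nmrk, ctx$Tm)
    p <- ifelse(sm[, 2L] < 0, 0,
                stats::pchisq(sm[, 1L], sm[, 2L], lower.tail = FALSE))
    list(idx = idx, p = p)
  }

  survivors <- function(sc, c1, c2) {
    best <- max(sc$p)
    keep <- which(sc$p >= params$p_ratio * best & sc$p > params$p_min)
    if (length(keep) == 0L) return(NULL)
    list(status = "candidates",
         ghap1 = c1[, sc$idx[keep, 1L], drop = FALSE],
         ghap2 = c2[, sc$idx[keep, 2L], drop = FALSE],
         p = sc$p[keep], n_genotyped = n,
         obs_key = obs_key, obs_count = obs_count,
         family = family)
  }

  inv1 <- which(colSums(matrix(!(sols1 %in% inventory), nrow = ploidy)) == 0L)
  inv2 <- which(colSums(matrix(!(sols2 %in% inventory), nrow = ploidy)) == 0L)
  npairs_inv <- if (selfing) length(inv1) else length(inv1) * length(inv2)
  npairs_all <- if (selfing) ncol(sols1) else ncol(sols1) * ncol(sols2)
  if (npairs_inv > params$max_parent_combs) {
    return(demoted("too_many_combinations"))
  }
  if (npairs_inv > 0L) {
    c1 <- sols1[, inv1, drop = FALSE]
    c2 <- if (selfing) c1 else sols2[, inv2, drop = FALSE]
    res <- survivors(score_set(c1, c2), c1, c2)
    if (!is.null(res)) return(res)
  }
  if (npairs_all > params$max_parent_combs) {
    return(demoted("too_many_combinations"))
  }
  res <- survivors(score_set(sols1, sols2), sols1, sols2)
  if (is.null(res)) return(demoted("no_acceptable_solution"))
  res
}

# ---- resolveGroupConflicts --------------------------------------------------

#' Resolve conflicts within a group of families linked by shared parents
#'
#' Iteratively removes the parental haplotype combination with the most
#' incompatible full-sib progeny until all remaining candidates are
#' mutually compatible; a family losing its last candidate is demoted
#' together with its non-shared parent. Among the surviving consistent
#' solution sets, the one maximizing the product of family P values is
#' chosen; under ties, only parents and offspring whose assignment is
#' identical under all co-optimal solutions are assigned.
#'
#' @param group List of family entries (as in [solve_one_fs()]) forming one
#'   connected component of the parent-sharing graph.
#' @param results List of [solve_one_fs()] results, parallel to `group`.
#' @param dos Block dosage matrix.
#' @param ploidy Even ploidy level.
#' @param params A [hap_params()] list.
#' @return List with `parent_assign` (named list id -> Ghap), `offspring`
#'   (named list id -> list(ghap, imputed)), `family_status` (tibble), and
#'   `demoted_ids` (individuals to be reanalyzed as unrelated material).
#' @export
resolve_group_conflicts <- function(group, results, dos, ploidy,
                                    params = hap_params()) {
  stopifnot(length(group) >= 1L, length(results) == length(group))
  nmrk <- nrow(dos)
  active <- which(vapply(results, function(r) r$status == "candidates",
                         logical(1L)))
  fam_status <- lapply(seq_along(group), function(i) {
    r <- results[[i]]
    tibble::tibble(family = group[[i]]$family,
                   status = if (r$status == "candidates") "solved" else "demoted",
                   reason = if (r$status == "candidates") NA_character_ else r$reason,
                   p_value = NA_real_, n_solutions = NA_integer_)
  })
  cands <- lapply(results, function(r) {
    if (r$status != "candidates") return(NULL)
    list(k1 = apply(r$ghap1, 2L, paste, collapse = ","),
         k2 = apply(r$ghap2, 2L, paste, collapse = ","),
         ghap1 = r$ghap1, ghap2 = r$ghap2, p = r$p, keep = rep(TRUE, length(r$p)))
  })
  fam_size <- vapply(group, function(f) length(f$offspring), integer(1L))

  parent_roles <- function(i) {
    c(stats::setNames(list("k1"), group[[i]]$parent1),
      if (!identical(group[[i]]$parent1, group[[i]]$parent2))
        stats::setNames(list("k2"), group[[i]]$parent2))
  }

  # iterative removal of the worst parental Ghap
  repeat {
    if (length(active) == 0L) break
    # tally unexplained progeny per (parent, ghap)
    tab <- list()
    for (i in active) {
      for (pid in unique(c(group[[i]]$parent1, group[[i]]$parent2))) {
        roles <- if (identical(pid, group[[i]]$parent1) &&
                     identical(pid, group[[i]]$parent2)) c("k1", "k2")
                 else if (identical(pid, group[[i]]$parent1)) "k1" else "k2"
        for (ro in roles) {
          ks <- unique(cands[[i]][[ro]][cands[[i]]$keep])
          for (kk in ks) {
            key <- paste0(pid, "|", kk)
            if (is.null(tab[[key]])) tab[[key]] <- 0L
          }
        }
      }
    }
    if (length(tab) == 0L) break
    for (key in names(tab)) {
      sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
      pid <- sp[1L]; kk <- sp[2L]
      for (i in active) {
        roles <- character(0)
        if (identical(pid, group[[i]]$parent1)) roles <- c(roles, "k1")
        if (identical(pid, group[[i]]$parent2)) roles <- c(roles, "k2")
        if (length(roles) == 0L) next
        is_sol <- any(vapply(roles, function(ro)
          any(cands[[i]][[ro]][cands[[i]]$keep] == kk), logical(1L)))
        if (!is_sol) tab[[key]] <- tab[[key]] + fam_size[i]
      }
    }
    worst_n <- max(unlist(tab))
    if (worst_n == 0L) break
    worst <- sort(names(tab)[unlist(tab) == worst_n])[1L]
    sp <- strsplit(worst, "|", fixed = TRUE)[[1L]]
    pid <- sp[1L]; kk <- sp[2L]
    for (i in active) {
      roles <- character(0)
      if (identical(pid, group[[i]]$parent1)) roles <- c(roles, "k1")
      if (identical(pid, group[[i]]$parent2)) roles <- c(roles, "k2")
      for (ro in roles) {
        cands[[i]]$keep <- cands[[i]]$keep & cands[[i]][[ro]] != kk
      }
    }
    lost <- active[vapply(active, function(i) !any(cands[[i]]$keep), logical(1L))]
    for (i in lost) {
      fam_status[[i]]$status <- "demoted"
      fam_status[[i]]$reason <- "incompatible_in_group"
    }
    active <- setdiff(active, lost)
  }

  # Optimal consistent solution sets over the remaining families.
  # Only parents occurring in more than one active family couple the
  # choices; conditional on their Ghaps, every family independently takes
  # its best-scoring compatible candidate. We therefore enumerate shared-
  # parent assignments only and record, per family, the set of co-optimal
  # candidates; ties multiply through this set rather than being expanded.
  fam_cand_sets <- stats::setNames(vector("list", length(group)),
                                   as.character(seq_along(group)))
  if (length(active)) {
    par_of <- lapply(active, function(i)
      unique(c(group[[i]]$parent1, group[[i]]$parent2)))
    all_par <- unlist(par_of)
    shared <- unique(all_par[duplicated(all_par)])
    shared_ghaps <- lapply(shared, function(pid) {
      ks <- lapply(active, function(i) {
        v <- character(0)
        if (identical(pid, group[[i]]$parent1))
          v <- c(v, cands[[i]]$k1[cands[[i]]$keep])
        if (identical(pid, group[[i]]$parent2))
          v <- c(v, cands[[i]]$k2[cands[[i]]$keep])
        v
      })
      ks <- ks[lengths(ks) > 0L]
      sort(Reduce(intersect, ks))
    })
    names(shared_ghaps) <- shared
    grids <- if (length(shared))
      expand.grid(shared_ghaps, stringsAsFactors = FALSE,
                  KEEP.OUT.ATTRS = FALSE)
    else data.frame(row.names = 1L)
    tol <- 1e-9
    best_logp <- -Inf
    best_rows <- list()  # list of per-family co-optimal candidate index sets
    nsig <- if (length(shared)) nrow(grids) else 1L
    for (ri in seq_len(nsig)) {
      sigma <- if (length(shared)) as.list(grids[ri, , drop = FALSE]) else list()
      logp <- 0
      sets <- list()
      feasible <- TRUE
      for (i in active) {
        f <- group[[i]]
        ok <- which(cands[[i]]$keep)
        if (!is.null(sigma[[f$parent1]]))
          ok <- ok[cands[[i]]$k1[ok] == sigma[[f$parent1]]]
        if (!is.null(sigma[[f$parent2]]))
          ok <- ok[cands[[i]]$k2[ok] == sigma[[f$parent2]]]
        if (length(ok) == 0L) { feasible <- FALSE; break }
        lp <- log(cands[[i]]$p[ok])
        mx <- max(lp)
        sets[[as.character(i)]] <- ok[lp >= mx - tol]
        logp <- logp + mx
      }
      if (!feasible) next
      if (logp > best_logp + tol) {
        best_logp <- logp
        best_rows <- list(sets)
      } else if (logp >= best_logp - tol) {
        best_rows <- c(best_rows, list(sets))
      }
    }
    if (length(best_rows) == 0L) {
      for (i in active) {
        fam_status[[i]]$status <- "demoted"
        fam_status[[i]]$reason <- "incompatible_in_group"
      }
      active <- integer(0)
    } else {
      for (i in active) {
        fam_cand_sets[[as.character(i)]] <-
          sort(unique(unlist(lapply(best_rows, `[[`, as.character(i)))))
      }
    }
  }

  # assignments: once per distinct co-optimal candidate of each family,
  # then keep only individuals assigned identically under all of them
  pa_votes <- list()
  off <- list()
  for (i in active) {
    f <- group[[i]]
    cis <- fam_cand_sets[[as.character(i)]]
    fam_status[[i]]$n_solutions <- length(cis)
    if (length(cis) == 1L) fam_status[[i]]$p_value <- cands[[i]]$p[cis]
    fam_assigns <- lapply(cis, function(ci) {
      g1 <- cands[[i]]$ghap1[, ci]
      g2 <- cands[[i]]$ghap2[, ci]
      assign_fs_offspring(f, g1, g2, dos, ploidy, params,
                          results[[i]]$obs_key, results[[i]]$obs_count,
                          results[[i]]$n_genotyped, cands[[i]]$p[ci])
    })
    ids <- Reduce(intersect, lapply(fam_assigns, names))
    for (id in ids) {
      vals <- lapply(fam_assigns, `[[`, id)
      if (all(vapply(vals, function(v)
        identical(v$ghap, vals[[1L]]$ghap), logical(1L)))) {
        off[[id]] <- vals[[1L]]
      }
    }
    for (ci in cis) {
      pa_votes[[f$parent1]] <- c(pa_votes[[f$parent1]],
                                 cands[[i]]$k1[ci])
      pa_votes[[f$parent2]] <- c(pa_votes[[f$parent2]],
                                 cands[[i]]$k2[ci])
    }
  }
  pa <- list()
  for (pid in names(pa_votes)) {
    u <- unique(pa_votes[[pid]])
    if (length(u) == 1L) {
      pa[[pid]] <- list(ghap = as.integer(strsplit(u, ",", fixed = TRUE)[[1L]]),
                        imputed = FALSE)
    }
  }

  demoted_ids <- character(0)
  dem <- which(vapply(fam_status, function(s) s$status == "demoted", logical(1L)))
  surviving_parents <- unique(unlist(lapply(active, function(i)
    c(group[[i]]$parent1, group[[i]]$parent2))))
  for (i in dem) {
    f <- group[[i]]
    demoted_ids <- c(demoted_ids, f$offspring,
                     setdiff(c(f$parent1, f$parent2), surviving_parents))
  }
  list(parent_assign = pa, offspring = off,
       family_status = dplyr::bind_rows(fam_status),
       demoted_ids = unique(demoted_ids))
}

# assignment + imputation of one family's offspring under a fixed parental
# solution. Returns named list id -> list(ghap, imputed).
assign_fs_offspring <- function(f, g1, g2, dos, ploidy, params,
                                obs_key, obs_count, n_genotyped, p_without) {
  nmrk <- nrow(dos)
  cls <- pair_ghap_classes(g1, g2, params$alpha, nmrk, ploidy)
  out <- list()
  imputed_keys <- integer(0)
  imputed_ids <- character(0)
  for (id in f$offspring) {
    g <- dos[, id]
    if (anyNA(g)) {
      if (all(is.na(g))) next
      obs <- which(!is.na(g))
      clsdos <- gmrk_unkey(cls$key, nmrk, ploidy)
      match_cls <- which(colSums(clsdos[obs, , drop = FALSE] !=
                                   g[obs]) == 0L)
      ukeys <- unique(cls$key[match_cls])
      if (length(ukeys) == 1L) {
        imputed_keys <- c(imputed_keys, ukeys)
        imputed_ids <- c(imputed_ids, id)
        if (length(match_cls) == 1L) {
          out[[id]] <- list(ghap = cls$ghap[, match_cls], imputed = TRUE)
        }
      }
    } else {
      key <- gmrk_index(g, ploidy)
      match_cls <- which(cls$key == key)
      if (length(match_cls) == 1L) {
        out[[id]] <- list(ghap = cls$ghap[, match_cls], imputed = FALSE)
      }
    }
  }
  if (length(imputed_ids)) {
    nfam <- length(f$offspring)
    accept <- (length(imputed_ids) / nfam) < params$impute_max_frac
    if (accept) {
      agg <- rowsum(rep(1L, length(imputed_keys)), imputed_keys)
      add_key <- as.integer(rownames(agg))
      add_cnt <- as.vector(agg[, 1L])
      keys2 <- union(obs_key, add_key)
      cnt2 <- obs_count[match(keys2, obs_key)]
      cnt2[is.na(cnt2)] <- 0
      cnt2 <- cnt2 + ifelse(is.na(match(keys2, add_key)), 0,
                            add_cnt[match(keys2, add_key)])
      info1 <- parent_ghap_info(g1, params$alpha, nmrk, ploidy)
      info2 <- parent_ghap_info(g2, params$alpha, nmrk, ploidy)
      bc <- pair_base_classes(info1, info2)
      p_with <- seg_pvalue_fast(keys2, cnt2, bc$key, bc$p,
                                n_genotyped + length(imputed_ids),
                                params$epsilon, ploidy, nmrk)
      accept <- p_with >= params$impute_p_ratio * p_without
    }
    if (!accept) {
      for (id in imputed_ids) out[[id]] <- NULL
    }
  }
  out
}

#' Impute a full-sib individual with missing dosages
#'
#' Given the accepted parental solution of its family, an offspring with
#' missing marker dosages is assigned the unique family-possible genotype
#' compatible with its non-missing dosages, if one exists.
#'
#' @param g Dosage vector of the individual (with `NA`s).
#' @param ghap1,ghap2 The family's parental haplotype combinations.
#' @param ploidy Even ploidy level.
#' @param params A [hap_params()] list (supplies `alpha`).
#' @return The imputed haplotype combination (integer vector) or `NULL`
#'   when not unique.
#' @export
impute_fs_indiv <- function(g, ghap1, ghap2, ploidy, params = hap_params()) {
  nmrk <- length(g)
  cls <- pair_ghap_classes(sort(as.integer(ghap1)), sort(as.integer(ghap2)),
                           params$alpha, nmrk, ploidy)
  obs <- which(!is.na(g))
  if (length(obs) == 0L) return(NULL)
  clsdos <- gmrk_unkey(cls$key, nmrk, ploidy)
  match_cls <- which(colSums(clsdos[obs, , drop = FALSE] != g[obs]) == 0L)
  if (length(unique(cls$key[match_cls])) != 1L) return(NULL)
  if (length(match_cls) != 1L) return(NULL)
  cls$ghap[, match_cls]
}
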