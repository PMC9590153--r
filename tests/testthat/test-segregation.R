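gd_named <- function(ghap, alpha) {
  d <- gamete_distribution(ghap, alpha)
  stats::setNames(d$prob, vapply(d$gamete, paste, character(1L),
                                 collapse = ","))
}

test_that("gamete distributions match closed forms", {
  # diploid: alpha irrelevant, 1/2 each
  for (a in c(0, 0.025, 0.5)) {
    expect_equal(gd_named(c(0, 1), a), c("0" = 0.5, "1" = 0.5))
  }
  # tetraploid homozygote
  expect_equal(gd_named(c(2, 2, 2, 2), 0.025), c("2,2" = 1))
  # tetraploid duplex at alpha = 0: 1/6, 2/3, 1/6
  expect_equal(gd_named(c(0, 0, 3, 3), 0),
               c("0,0" = 1 / 6, "0,3" = 2 / 3, "3,3" = 1 / 6))
  # with double reduction the homozygous gametes gain alpha/2 each
  a <- 0.1
  expect_equal(gd_named(c(0, 0, 3, 3), a),
               c("0,0" = (1 - a) / 6 + a / 2, "0,3" = (1 - a) * 2 / 3,
                 "3,3" = (1 - a) / 6 + a / 2))
  # fully heteroallelic: DR gametes exist only when alpha > 0
  expect_false("1,1" %in% names(gd_named(c(1, 2, 4, 8), 0)))
  d <- gd_named(c(1, 2, 4, 8), 0.2)
  expect_equal(unname(d["1,1"]), 0.2 / 4)
})

test_that("gamete and progeny distributions are normalized", {
  set.seed(10)
  for (ploidy in c(2L, 4L, 6L)) {
    for (i in 1:8) {
      g1 <- sort(sample(0:7, ploidy, replace = TRUE))
      g2 <- sort(sample(0:7, ploidy, replace = TRUE))
      a <- stats::runif(1, 0, 0.3)
      expect_equal(sum(gamete_distribution(g1, a)$prob), 1, tolerance = 1e-12)
      pd <- progeny_ghap_distribution(g1, g2, a)
      expect_equal(sum(pd$prob), 1, tolerance = 1e-12)
      expect_true(all(lengths(pd$ghap) == ploidy))
    }
  }
})

test_that("progeny distributions match Mendelian closed forms", {
  pd_named <- function(g1, g2, a) {
    d <- progeny_ghap_distribution(g1, g2, a)
    stats::setNames(d$prob, vapply(d$ghap, paste, character(1L),
                                   collapse = ","))
  }
  expect_equal(pd_named(c(0, 0, 0, 0), c(0, 0, 0, 0), 0.025),
               c("0,0,0,0" = 1))
  # diploid backcross
  expect_equal(pd_named(c(0, 1), c(0, 0), 0),
               c("0,0" = 0.5, "0,1" = 0.5))
  # tetraploid duplex x nulliplex
  expect_equal(pd_named(c(0, 0, 1, 1), c(0, 0, 0, 0), 0),
               c("0,0,0,0" = 1 / 6, "0,0,0,1" = 2 / 3, "0,0,1,1" = 1 / 6))
})

test_that("the dosage-error model spreads to adjacent dosages only", {
  one <- function(g) tibble::tibble(ghap = list(as.integer(g)), prob = 1)
  # epsilon = 0: pure push-forward
  d0 <- expected_gmrk_distribution(progeny_ghap_distribution(c(0, 0, 1, 1),
                                                             c(0, 0, 0, 0), 0),
                                   0, 4, 1)
  expect_equal(vapply(d0$gmrk, identity, integer(1L)), c(0L, 1L, 2L))
  expect_equal(d0$prob, c(1 / 6, 2 / 3, 1 / 6))
  # boundary class: all error mass to the single neighbor
  db <- expected_gmrk_distribution(one(c(0, 0, 0, 0)), 0.025, 4, 1)
  expect_equal(db$prob, c(0.975, 0.025))
  # interior class: split equally
  di <- expected_gmrk_distribution(one(c(0, 0, 3, 3)), 0.025, 4, 2)
  m <- do.call(cbind, di$gmrk)
  k <- di$prob[m[1L, ] == 2 & m[2L, ] == 2]
  expect_equal(k, 0.975^2)
  k1 <- di$prob[m[1L, ] == 1 & m[2L, ] == 2]
  expect_equal(k1, 0.0125 * 0.975)
  expect_equal(sum(di$prob), 1, tolerance = 1e-12)
})

test_that("chi-squared P values match hand computations", {
  ob <- tibble::tibble(gmrk = list(0L, 1L), count = c(50L, 50L))
  ex <- tibble::tibble(gmrk = list(0L, 1L), prob = c(0.5, 0.5))
  expect_equal(fs_segregation_pvalue(ob, ex, 100), 1)
  ob2 <- tibble::tibble(gmrk = list(0L, 1L), count = c(30L, 70L))
  expect_equal(fs_segregation_pvalue(ob2, ex, 100),
               stats::pchisq(16, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(fs_segregation_pvalue(ob2, ex, 100), 6.33e-5,
               tolerance = 1e-2)
  expect_error(fs_segregation_pvalue(ob2, ex, 50), "sum to n")
})

test_that("P values are invariant under category permutation", {
  set.seed(11)
  gm <- list(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(1L, 2L))
  pr <- c(0.4, 0.3, 0.2, 0.1)
  ct <- c(10L, 12L, 5L, 3L)
  p0 <- fs_segregation_pvalue(tibble::tibble(gmrk = gm, count = ct),
                              tibble::tibble(gmrk = gm, prob = pr), 30)
  for (i in 1:5) {
    o <- sample(4L)
    p1 <- fs_segregation_pvalue(tibble::tibble(gmrk = gm[o], count = ct[o]),
                                tibble::tibble(gmrk = gm[sample(4L)],
                                               prob = pr[sample(4L)]), 30)
  }
  # permuting observed rows only (same pairing) leaves P unchanged
  o <- sample(4L)
  p2 <- fs_segregation_pvalue(tibble::tibble(gmrk = gm[o], count = ct[o]),
                              tibble::tibble(gmrk = gm, prob = pr), 30)
  expect_equal(p2, p0, tolerance = 1e-12)
})

test_that("rare expected classes and unexpected observations are pooled", {
  # 3 expected classes, one with expected < 1; one observed class entirely
  # outside the expectation
  ex <- tibble::tibble(gmrk = list(0L, 1L, 2L), prob = c(0.59, 0.4, 0.01))
  ob <- tibble::tibble(gmrk = list(0L, 1L, 3L), count = c(30L, 18L, 2L))
  p <- fs_segregation_pvalue(ob, ex, 50)
  # pooled category: E = 50 * 0.01 = 0.5, O = 2; kept: (30, 29.5), (18, 20)
  stat <- (30 - 29.5)^2 / 29.5 + (18 - 20)^2 / 20 + (2 - 0.5)^2 / 0.5
  expect_equal(p, stats::pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # impossible observation with zero pooled expectation: P = 0
  ex0 <- tibble::tibble(gmrk = list(0L, 1L), prob = c(0.6, 0.4))
  ob0 <- tibble::tibble(gmrk = list(0L, 4L), count = c(49L, 1L))
  expect_equal(fs_segregation_pvalue(ob0, ex0, 50), 0)
})

test_that("the internal scorer agrees with the reference computation", {
  set.seed(12)
  ploidy <- 4L
  for (nmrk in 2:3) {
    for (i in 1:10) {
      g1 <- sort(sample(0:(2^nmrk - 1), ploidy, replace = TRUE))
      g2 <- sort(sample(0:(2^nmrk - 1), ploidy, replace = TRUE))
      a <- 0.025
      eps <- c(0, 0.025, 0.1)[1 + i %% 3]
      n <- 40L
      off <- simulate_cross(g1, g2, n, alpha = a)
      dosO <- mrkdos_of_hapcomb(off, nmrk)
      if (!is.matrix(dosO)) dosO <- matrix(dosO, nrow = nmrk)
      keys <- haplodose:::gmrk_keys(dosO, ploidy)
      agg <- haplodose:::key_aggregate(keys, rep(1, n))
      # reference: full error expansion, tibble interface
      ex <- expected_gmrk_distribution(progeny_ghap_distribution(g1, g2, a),
                                       eps, ploidy, nmrk)
      obs <- tibble::tibble(
        gmrk = lapply(seq_along(agg$key),
                      function(j) haplodose:::gmrk_unkey(agg$key[j], nmrk,
                                                         ploidy)[, 1L]),
        count = agg$p)
      p_ref <- fs_segregation_pvalue(obs, ex, n)
      p_fast <- haplodose:::seg_pvalue_fast(
        agg$key, agg$p,
        baseK = local({
          bc <- haplodose:::pair_base_classes(
            haplodose:::parent_ghap_info(g1, a, nmrk, ploidy),
            haplodose:::parent_ghap_info(g2, a, nmrk, ploidy))
          bc$key
        }),
        baseP = local({
          bc <- haplodose:::pair_base_classes(
            haplodose:::parent_ghap_info(g1, a, nmrk, ploidy),
            haplodose:::parent_ghap_info(g2, a, nmrk, ploidy))
          bc$p
        }),
        n = n, epsilon = eps, ploidy = ploidy, nmrk = nmrk)
      expect_equal(p_fast, p_ref, tolerance = 1e-9)
      # and the C++ kernel agrees with both
      info1 <- haplodose:::parent_ghap_info(g1, a, nmrk, ploidy)
      info2 <- haplodose:::parent_ghap_info(g2, a, nmrk, ploidy)
      Tm <- haplodose:::dosage_error_matrix(ploidy, eps)
      sm <- haplodose:::score_pairs_cpp(
        list(as.numeric(info1$key)), list(as.numeric(info1$p)),
        list(as.numeric(info2$key)), list(as.numeric(info2$p)),
        matrix(c(1L, 1L), 1), as.numeric(agg$key), as.numeric(agg$p),
        n, eps, ploidy, nmrk, Tm)
      p_cpp <- if (sm[1, 2] < 0) 0 else
        stats::pchisq(sm[1, 1], sm[1, 2], lower.tail = FALSE)
      expect_equal(p_cpp, p_ref, tolerance = 1e-9)
    }
  }
})

make_family <- function(g1, g2, n, nmrk, alpha = 0.025, seed = 1) {
  set.seed(seed)
  off <- simulate_cross(g1, g2, n, alpha = alpha)
  dos <- cbind(mrkdos_of_hapcomb(g1, nmrk), mrkdos_of_hapcomb(g2, nmrk),
               mrkdos_of_hapcomb(off, nmrk))
  dos <- matrix(as.integer(dos), nrow = nmrk)
  dimnames(dos) <- list(paste0("m", seq_len(nmrk)),
                        c("P1", "P2", sprintf("O%02d", seq_len(n))))
  list(dos = dos,
       fam = list(family = "F1", parent1 = "P1", parent2 = "P2",
                  offspring = sprintf("O%02d", seq_len(n))),
       off = off)
}

test_that("a family with forced homozygous parents is solved uniquely", {
  nmrk <- 2L
  mf <- make_family(c(0L, 0L, 0L, 0L), c(3L, 3L, 3L, 3L), 30, nmrk)
  r <- solve_one_fs(mf$fam, mf$dos, inventory = c(0L, 3L), ploidy = 4)
  expect_equal(r$status, "candidates")
  expect_equal(ncol(r$ghap1), 1L)
  expect_equal(unname(r$ghap1[, 1L]), c(0L, 0L, 0L, 0L))
  expect_equal(unname(r$ghap2[, 1L]), c(3L, 3L, 3L, 3L))
  # the pooled error-mass category costs a little even on exact data
  expect_gt(r$p[1L], 0.05)
})

test_that("missing parental dosages demote the family", {
  mf <- make_family(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 3L), 20, 2)
  mf$dos["m1", "P1"] <- NA_integer_
  r <- solve_one_fs(mf$fam, mf$dos, inventory = 0:3, ploidy = 4)
  expect_equal(r$status, "demoted")
  expect_equal(r$reason, "missing_parent_dosages")
})

test_that("exceeding the parental combination cap demotes the family", {
  mf <- make_family(c(1L, 2L, 4L, 7L), c(0L, 3L, 5L, 6L), 20, 3)
  r <- solve_one_fs(mf$fam, mf$dos, inventory = integer(), ploidy = 4,
                    params = hap_params(max_parent_combs = 10))
  expect_equal(r$status, "demoted")
  expect_equal(r$reason, "too_many_combinations")
})

test_that("unknown ids raise an input error", {
  mf <- make_family(c(0L, 0L, 0L, 0L), c(3L, 3L, 3L, 3L), 5, 2)
  bad <- mf$fam
  bad$offspring <- c(bad$offspring, "ghost")
  expect_error(solve_one_fs(bad, mf$dos, integer(), 4), "unknown")
})

test_that("the true parental pair survives the filters on exact data", {
  set.seed(13)
  nmrk <- 3L
  for (i in 1:5) {
    g1 <- sort(sample(0:7, 4, replace = TRUE))
    g2 <- sort(sample(0:7, 4, replace = TRUE))
    mf <- make_family(g1, g2, 50, nmrk, alpha = 0.025, seed = 100 + i)
    r <- solve_one_fs(mf$fam, mf$dos, inventory = sort(unique(c(g1, g2))),
                      ploidy = 4)
    expect_equal(r$status, "candidates")
    k1 <- apply(r$ghap1, 2L, paste, collapse = ",")
    k2 <- apply(r$ghap2, 2L, paste, collapse = ",")
    expect_true(any(k1 == paste(g1, collapse = ",") &
                      k2 == paste(g2, collapse = ",")))
  }
})

test_that("assigned offspring always reproduce their dosages", {
  set.seed(14)
  nmrk <- 3L
  g1 <- c(0L, 1L, 2L, 4L)
  g2 <- c(0L, 0L, 3L, 7L)
  mf <- make_family(g1, g2, 40, nmrk)
  grp <- list(mf$fam)
  res <- list(solve_one_fs(mf$fam, mf$dos, sort(unique(c(g1, g2))), 4))
  rg <- resolve_group_conflicts(grp, res, mf$dos, 4)
  for (id in names(rg$offspring)) {
    expect_equal(mrkdos_of_hapcomb(rg$offspring[[id]]$ghap, nmrk),
                 unname(mf$dos[, id]))
  }
})

test_that("group conflict resolution passes single solutions through", {
  mf <- make_family(c(0L, 0L, 0L, 0L), c(3L, 3L, 3L, 3L), 20, 2)
  res <- list(solve_one_fs(mf$fam, mf$dos, c(0L, 3L), 4))
  rg <- resolve_group_conflicts(list(mf$fam), res, mf$dos, 4)
  expect_equal(rg$family_status$status, "solved")
  expect_equal(rg$family_status$n_solutions, 1L)
  expect_equal(rg$parent_assign$P1$ghap, c(0L, 0L, 0L, 0L))
  expect_equal(rg$parent_assign$P2$ghap, c(3L, 3L, 3L, 3L))
  # all offspring of a homozygous x homozygous cross are assignable
  expect_equal(length(rg$offspring), 20L)
})

test_that("shared parents select the consistent candidate", {
  # two families sharing P1; the shared-parent assignment must be the one
  # Ghap compatible with both offspring segregations
  set.seed(15)
  nmrk <- 2L
  gA <- c(0L, 1L, 2L, 3L)
  gB <- c(0L, 0L, 3L, 3L)
  gC <- c(1L, 1L, 2L, 2L)
  o1 <- simulate_cross(gA, gB, 40, alpha = 0)
  o2 <- simulate_cross(gA, gC, 40, alpha = 0)
  dos <- cbind(mrkdos_of_hapcomb(gA, nmrk), mrkdos_of_hapcomb(gB, nmrk),
               mrkdos_of_hapcomb(gC, nmrk),
               mrkdos_of_hapcomb(o1, nmrk), mrkdos_of_hapcomb(o2, nmrk))
  dos <- matrix(as.integer(dos), nrow = nmrk)
  dimnames(dos) <- list(c("m1", "m2"),
                        c("PA", "PB", "PC", sprintf("X%02d", 1:40),
                          sprintf("Y%02d", 1:40)))
  f1 <- list(family = "F1", parent1 = "PA", parent2 = "PB",
             offspring = sprintf("X%02d", 1:40))
  f2 <- list(family = "F2", parent1 = "PA", parent2 = "PC",
             offspring = sprintf("Y%02d", 1:40))
  inv <- sort(unique(c(gA, gB, gC)))
  res <- list(solve_one_fs(f1, dos, inv, 4), solve_one_fs(f2, dos, inv, 4))
  rg <- resolve_group_conflicts(list(f1, f2), res, dos, 4)
  expect_equal(sort(rg$family_status$status), c("solved", "solved"))
  if (!is.null(rg$parent_assign$PA)) {
    expect_equal(rg$parent_assign$PA$ghap, gA)
  }
})

test_that("imputation fills unique family genotypes only", {
  g1 <- c(0L, 0L, 0L, 0L)
  g2 <- c(3L, 3L, 3L, 3L)
  # offspring are all {0,0,3,3}; with one missing marker the family allows
  # a single genotype
  g <- c(2L, NA)
  expect_equal(impute_fs_indiv(g, g1, g2, 4), c(0L, 0L, 3L, 3L))
  # two compatible family genotypes: no imputation
  g1b <- c(0L, 0L, 1L, 1L)
  gb <- c(1L, NA)
  expect_null(impute_fs_indiv(gb, g1b, g2, 4))
})

test_that("families with too many imputed offspring reject imputations", {
  nmrk <- 2L
  g1 <- c(0L, 0L, 0L, 0L)
  g2 <- c(3L, 3L, 3L, 3L)
  mf <- make_family(g1, g2, 10, nmrk)
  # blank one marker for 6 of 10 offspring: 60% > 50% cap
  mf$dos["m1", 3:8] <- NA_integer_
  res <- list(solve_one_fs(mf$fam, mf$dos, c(0L, 3L), 4))
  rg <- resolve_group_conflicts(list(mf$fam), res, mf$dos, 4)
  expect_false(any(vapply(rg$offspring, `[[`, logical(1L), "imputed")))
  # with only 2 blanked, imputation is accepted
  mf2 <- make_family(g1, g2, 10, nmrk)
  mf2$dos["m1", 3:4] <- NA_integer_
  res2 <- list(solve_one_fs(mf2$fam, mf2$dos, c(0L, 3L), 4))
  rg2 <- resolve_group_conflicts(list(mf2$fam), res2, mf2$dos, 4)
  imp <- vapply(rg2$offspring, `[[`, logical(1L), "imputed")
  expect_equal(sum(imp), 2L)
})
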