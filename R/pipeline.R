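# Orchestration: per-haploblock haplotyping over a whole population.

#' Group full-sib families linked through shared parents
#'
#' @param families A tibble with columns `family`, `parent1`, `parent2`
#'   and list-column `offspring` (character ids).
#' @return List of integer vectors: row indices of `families` forming the
#'   connected components of the parent-sharing graph, in order of first
#'   appearance.
#' @export
group_fs_families <- function(families) {
  validate_families(families)
  n <- nrow(families)
  if (n == 0L) return(list())
  parents <- unique(c(families$parent1, families$parent2))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (p in parents) {
    in_p <- which(families$parent1 == p | families$parent2 == p)
    if (length(in_p) > 1L) {
      r <- find(in_p[1L])
      for (j in in_p[-1L]) comp[find(j)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  idx <- split(seq_len(n), match(roots, unique(roots)))
  unname(idx)
}

validate_families <- function(families) {
  stopifnot(is.data.frame(families),
            all(c("family", "parent1", "parent2", "offspring") %in%
                  names(families)))
  off <- unlist(families$offspring, use.names = FALSE)
  if (anyDuplicated(off)) {
    stop("an offspring individual belongs to more than one full-sib family",
         call. = FALSE)
  }
  par <- unique(c(families$parent1, families$parent2))
  if (any(off %in% par)) {
    stop("parents must be distinct from offspring", call. = FALSE)
  }
  invisible(families)
}

#' Infer haploblock genotypes for a population
#'
#' Main entry point. Each haploblock is processed independently in three
#' stages: (1) a parsimonious inventory of haplotypes present in the
#' population is built from the dosages alone; (2) full-sib families are
#' haplotyped by scoring candidate parental haplotype combinations against
#' the observed offspring segregation (families that cannot be solved are
#' demoted to unrelated material for that block); (3) remaining material
#' is haplotyped by parsimony, seeded with the haplotypes confirmed in the
#' family solutions. With no (or ignored) families, processing goes
#' directly to stage 3. Results are deterministic for identical inputs.
#'
#' @param dosages Integer matrix of SNP dosages: markers x individuals,
#'   with row and column names; entries in `[0, ploidy]` or `NA`.
#' @param blocks Named list mapping block name to an ordered character
#'   vector of marker names, or a data frame with columns `block`,
#'   `marker`.
#' @param ploidy Even ploidy level shared by all individuals.
#' @param families Optional full-sib specification: tibble with columns
#'   `family`, `parent1`, `parent2`, list-column `offspring`.
#' @param params A [hap_params()] list.
#' @param known_haps Optional a-priori haplotypes: integer vector applied
#'   to every block, or named list block -> codes.
#' @param use_fs Use the family structure (set `FALSE` to haplotype all
#'   individuals as unrelated, for comparison).
#' @param verbose Print per-block progress.
#' @return An object of class `hap_result`: list with tibbles
#'   `assignments` (block, indiv, category, stage, imputed, assigned,
#'   `ghap` list-column), `inventory` (block, hap, provenance),
#'   `families` (block, family, status, reason, p_value, n_solutions), and
#'   `blocks` (block, nmrk, error), plus `ploidy` and `params`.
#' @export
infer_haplotypes <- function(dosages, blocks, ploidy, families = NULL,
                             params = hap_params(), known_haps = NULL,
                             use_fs = TRUE, verbose = FALSE) {
  ploidy <- check_ploidy(ploidy)
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  blocks <- as_block_list(blocks)
  if (!is.null(families)) validate_families(families)
  inds <- colnames(dosages)
  category <- categorize_individuals(inds, families)

  asn_rows <- list(); inv_rows <- list(); fam_rows <- list(); blk_rows <- list()
  for (bi in seq_along(blocks)) {
    bname <- names(blocks)[bi]
    mk <- blocks[[bi]]
    if (!all(mk %in% rownames(dosages))) {
      stop("block ", bname, " references unknown markers", call. = FALSE)
    }
    res <- tryCatch(
      hap_one_block(dosages[mk, , drop = FALSE], ploidy, families, params,
                    block_known_haps(known_haps, bname), use_fs),
      haplodose_capacity_error = function(e) e)
    if (inherits(res, "error")) {
      blk_rows[[bi]] <- tibble::tibble(block = bname, nmrk = length(mk),
                                       error = conditionMessage(res))
      next
    }
    blk_rows[[bi]] <- tibble::tibble(block = bname, nmrk = length(mk),
                                     error = NA_character_)
    res$assignments$block <- bname
    res$inventory$block <- bname
    if (nrow(res$families)) res$families$block <- bname
    asn_rows[[bi]] <- res$assignments
    inv_rows[[bi]] <- res$inventory
    fam_rows[[bi]] <- res$families
    if (verbose) {
      message(sprintf("block %s: %d/%d assigned, %d haplotypes", bname,
                      sum(res$assignments$assigned),
                      nrow(res$assignments), nrow(res$inventory)))
    }
  }
  asn <- dplyr::bind_rows(asn_rows)
  if (nrow(asn)) {
    asn$category <- category[asn$indiv]
    asn <- asn[, c("block", "indiv", "category", "stage", "imputed",
                   "assigned", "ghap")]
  }
  structure(list(assignments = asn,
                 inventory = dplyr::bind_rows(inv_rows),
                 families = dplyr::bind_rows(fam_rows),
                 blocks = dplyr::bind_rows(blk_rows),
                 ploidy = ploidy, params = params),
            class = "hap_result")
}

as_block_list <- function(blocks) {
  if (is.data.frame(blocks)) {
    stopifnot(all(c("block", "marker") %in% names(blocks)))
    blocks <- split(blocks$marker, factor(blocks$block,
                                          levels = unique(blocks$block)))
  }
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  blocks
}

block_known_haps <- function(known_haps, bname) {
  if (is.null(known_haps)) return(integer(0))
  if (is.list(known_haps)) {
    kh <- known_haps[[bname]]
    if (is.null(kh)) integer(0) else as.integer(kh)
  } else as.integer(known_haps)
}

categorize_individuals <- function(inds, families) {
  cat <- stats::setNames(rep("other", length(inds)), inds)
  if (!is.null(families) && nrow(families)) {
    off <- unlist(families$offspring, use.names = FALSE)
    par <- unique(c(families$parent1, families$parent2))
    cat[intersect(off, inds)] <- "fs_individual"
    cat[intersect(par, inds)] <- "fs_parent"
  }
  cat
}

# haplotyping of a single block
hap_one_block <- function(dos, ploidy, families, params, known, use_fs) {
  nmrk <- nrow(dos)
  if (nmrk > default_max_nmrk(ploidy)) {
    stop(structure(
      class = c("haplodose_capacity_error", "error", "condition"),
      list(message = sprintf("block of %d markers exceeds the %d-marker limit at ploidy %d",
                             nmrk, default_max_nmrk(ploidy), ploidy),
           call = NULL)))
  }
  # full table pays off for small blocks only; larger blocks use direct
  # per-genotype enumeration (memoized through dosage_groups)
  table <- if (count_all_hapcombs(nmrk, ploidy) <= 1e5)
    get_hapcomb_table(nmrk, ploidy) else NULL
  inds <- colnames(dos)
  ghap_list <- stats::setNames(vector("list", length(inds)), inds)
  stage <- stats::setNames(rep(NA_character_, length(inds)), inds)
  imputed <- stats::setNames(rep(FALSE, length(inds)), inds)
  fam_status <- tibble::tibble()
  confirmed <- sort(unique(as.integer(known)))
  stage3_ids <- inds
  prov_known <- NULL

  has_fs <- use_fs && !is.null(families) && nrow(families) > 0L
  if (has_fs) {
    s1 <- infer_haps_nofs(dos, ploidy, prior = known, params = params,
                          table = table)
    groups <- group_fs_families(families)
    memo <- new.env(parent = emptyenv())
    demoted_ids <- character(0)
    fs_ids <- character(0)
    for (gi in groups) {
      grp <- lapply(gi, function(i) list(
        family = families$family[i], parent1 = families$parent1[i],
        parent2 = families$parent2[i], offspring = families$offspring[[i]]))
      results <- lapply(grp, solve_one_fs, dos = dos, inventory = s1$haps,
                        ploidy = ploidy, params = params, table = table,
                        memo = memo)
      rg <- resolve_group_conflicts(grp, results, dos, ploidy, params)
      for (id in names(rg$parent_assign)) {
        ghap_list[[id]] <- rg$parent_assign[[id]]$ghap
        stage[id] <- "fs"
      }
      for (id in names(rg$offspring)) {
        ghap_list[[id]] <- rg$offspring[[id]]$ghap
        stage[id] <- "fs"
        imputed[id] <- rg$offspring[[id]]$imputed
      }
      fam_status <- dplyr::bind_rows(fam_status, rg$family_status)
      demoted_ids <- c(demoted_ids, rg$demoted_ids)
      solved <- rg$family_status$family[rg$family_status$status == "solved"]
      for (fe in grp) {
        if (fe$family %in% solved) {
          fs_ids <- c(fs_ids, fe$parent1, fe$parent2, fe$offspring)
        }
      }
    }
    confirmed <- sort(unique(c(confirmed,
                               unlist(lapply(names(ghap_list), function(id)
                                 if (!is.null(ghap_list[[id]]) &&
                                     stage[id] == "fs" &&
                                     id %in% c(families$parent1, families$parent2))
                                   ghap_list[[id]] else NULL)))))
    stage3_ids <- setdiff(inds, unique(fs_ids))
    stage3_ids <- union(intersect(demoted_ids, inds), stage3_ids)
  }

  if (length(stage3_ids)) {
    d3 <- dos[, stage3_ids, drop = FALSE]
    if (any(colSums(!is.na(d3)) > 0L)) {
      s3 <- haplotype_unrelated(d3, ploidy, confirmed = confirmed,
                                params = params, table = table)
      for (id in stage3_ids) {
        g <- s3$assign[, id]
        if (!anyNA(g)) {
          ghap_list[[id]] <- as.integer(g)
          stage[id] <- "unrelated"
        }
      }
      inv_codes <- s3$haps
      inv_prov <- s3$provenance
    } else {
      inv_codes <- confirmed
      inv_prov <- rep("a_priori", length(confirmed))
    }
  } else {
    inv_codes <- confirmed
    inv_prov <- rep("a_priori", length(confirmed))
  }

  assigned <- !vapply(ghap_list, is.null, logical(1L))
  list(assignments = tibble::tibble(
         block = NA_character_, indiv = inds, stage = unname(stage),
         imputed = unname(imputed), assigned = unname(assigned),
         ghap = unname(ghap_list)),
       inventory = tibble::tibble(block = NA_character_, hap = inv_codes,
                                  provenance = inv_prov),
       families = fam_status)
}

#' @export
print.hap_result <- function(x, ...) {
  nb <- nrow(x$blocks)
  cat(sprintf("<hap_result> ploidy %d, %d block(s), %d individuals\n",
              x$ploidy, nb,
              length(unique(x$assignments$indiv))))
  if (nrow(x$assignments)) {
    cat(sprintf("  assigned: %.1f%% of individual-block combinations\n",
                100 * mean(x$assignments$assigned)))
  }
  if (nrow(x$families)) {
    cat(sprintf("  families: %d solved, %d demoted (over blocks)\n",
                sum(x$families$status == "solved"),
                sum(x$families$status == "demoted")))
  }
  invisible(x)
}

#' Merge replicate samples into consensus individuals
#'
#' For each marker, replicate samples of one individual are merged into
#' the unique non-missing dosage value; conflicting non-missing values
#' yield a missing consensus.
#'
#' @param dosages Markers x samples dosage matrix.
#' @param replicates A data frame with columns `sample`, `indiv` mapping
#'   (a subset of) sample columns to individuals.
#' @return Dosage matrix with one column per individual; samples not in
#'   the map are kept unchanged.
#' @export
merge_replicates <- function(dosages, replicates) {
  stopifnot(is.matrix(dosages),
            all(c("sample", "indiv") %in% names(replicates)))
  replicates <- replicates[replicates$sample %in% colnames(dosages), ]
  keep <- setdiff(colnames(dosages), replicates$sample)
  merged <- vapply(split(replicates$sample, replicates$indiv),
                   function(smp) {
                     sub <- dosages[, smp, drop = FALSE]
                     apply(sub, 1L, function(v) {
                       u <- unique(v[!is.na(v)])
                       if (length(u) == 1L) u else NA_integer_
                     })
                   }, integer(nrow(dosages)))
  if (!is.matrix(merged)) merged <- matrix(merged, nrow = nrow(dosages),
                                           dimnames = list(rownames(dosages),
                                                           unique(replicates$indiv)))
  out <- cbind(dosages[, keep, drop = FALSE], merged)
  out
}

#' Check parent-offspring compatibility of haplotype assignments
#'
#' An offspring assignment is compatible with two assigned parents when it
#' can be split into two gametes, each producible by the respective parent
#' under the gamete model (double-reduction gametes count as producible
#' when `alpha > 0`). With one assigned parent only one gamete is
#' constrained. Individuals (or all their pedigree parents) lacking
#' assignments are non-checkable.
#'
#' @param result A `hap_result`.
#' @param pedigree Data frame with columns `indiv`, `parent1`, `parent2`
#'   (missing parent = `NA`).
#' @param alpha Double-reduction frequency for the compatibility check
#'   (default: the value in `result$params`).
#' @return A tibble (block, indiv, status) with status `match`,
#'   `conflict`, or `non_checkable`.
#' @export
check_parent_offspring <- function(result, pedigree,
                                   alpha = result$params$alpha) {
  stopifnot(inherits(result, "hap_result"),
            all(c("indiv", "parent1", "parent2") %in% names(pedigree)))
  ploidy <- result$ploidy
  k <- ploidy %/% 2L
  splits <- utils::combn(ploidy, k)
  supp_memo <- new.env(parent = emptyenv())
  gam_keys <- function(ghap) {
    id <- paste(ghap, collapse = ",")
    v <- supp_memo[[id]]
    if (is.null(v)) {
      s <- gamete_support_int(ghap, alpha)
      v <- apply(s$g, 2L, paste, collapse = ",")
      supp_memo[[id]] <- v
    }
    v
  }
  rows <- list()
  for (b in unique(result$assignments$block)) {
    sub <- result$assignments[result$assignments$block == b, ]
    amap <- stats::setNames(sub$ghap, sub$indiv)
    has <- stats::setNames(sub$assigned, sub$indiv)
    ped <- pedigree[pedigree$indiv %in% sub$indiv &
                      (!is.na(pedigree$parent1) | !is.na(pedigree$parent2)), ]
    if (nrow(ped) == 0L) next
    status <- character(nrow(ped))
    for (r in seq_len(nrow(ped))) {
      id <- ped$indiv[r]
      pars <- c(ped$parent1[r], ped$parent2[r])
      pars <- pars[!is.na(pars)]
      pars_ok <- pars[pars %in% names(has) & vapply(pars, function(p)
        isTRUE(has[[p]]), logical(1L))]
      if (!isTRUE(has[[id]]) || length(pars_ok) == 0L) {
        status[r] <- "non_checkable"
        next
      }
      off <- amap[[id]]
      halves <- apply(splits, 2L, function(ix)
        paste(sort(off[ix]), collapse = ","))
      comp_halves <- apply(splits, 2L, function(ix)
        paste(sort(off[-ix]), collapse = ","))
      ok <- FALSE
      if (length(pars_ok) == 2L) {
        s1 <- gam_keys(amap[[pars_ok[1L]]])
        s2 <- gam_keys(amap[[pars_ok[2L]]])
        ok <- any(halves %in% s1 & comp_halves %in% s2)
      } else {
        s1 <- gam_keys(amap[[pars_ok[1L]]])
        ok <- any(halves %in% s1)
      }
      status[r] <- if (ok) "match" else "conflict"
    }
    rows[[b]] <- tibble::tibble(block = b, indiv = ped$indiv,
                                status = status)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(block = character(), indiv = character(),
                          status = character())
  }
  out
}

#' Summary statistics of a haplotyping run
#'
#' Per block and per category of material (full-sib individuals, full-sib
#' parents, other, and all combined): percentage of fully genotyped
#' individuals (no missing dosages in the block), percentage haplotyped,
#' and -- when a pedigree check report is supplied -- percentage checkable
#' and percentage matching their parents, with the corresponding counts.
#'
#' @param result A `hap_result`.
#' @param dosages The dosage matrix the result was computed from.
#' @param blocks The haploblock definition used.
#' @param report Optional output of [check_parent_offspring()].
#' @return An object of class `hap_summary`: list with tibbles `by_block`
#'   (block x category rows) and `overall` (category rows, averaged over
#'   blocks as well as pooled over individuals).
#' @export
summarize_haplotyping <- function(result, dosages, blocks, report = NULL) {
  stopifnot(inherits(result, "hap_result"))
  blocks <- as_block_list(blocks)
  asn <- result$assignments
  rows <- list()
  for (b in unique(asn$block)) {
    sub <- asn[asn$block == b, ]
    full <- colSums(is.na(dosages[blocks[[b]], sub$indiv, drop = FALSE])) == 0L
    nhaps <- length(unique(unlist(sub$ghap[sub$assigned])))
    rep_b <- if (!is.null(report)) report[report$block == b, ] else NULL
    for (cat in c("fs_individual", "fs_parent", "other", "all")) {
      ss <- if (cat == "all") sub else sub[sub$category == cat, ]
      if (nrow(ss) == 0L) next
      ck <- mt <- cf <- nc <- NA_integer_
      if (!is.null(rep_b)) {
        rr <- rep_b[rep_b$indiv %in% ss$indiv, ]
        mt <- sum(rr$status == "match")
        cf <- sum(rr$status == "conflict")
        nc <- sum(rr$status == "non_checkable")
        ck <- mt + cf
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = b, category = cat, n = nrow(ss),
        n_haplotypes = nhaps,
        pct_fully_genotyped = 100 * mean(full[ss$indiv]),
        pct_haplotyped = 100 * mean(ss$assigned),
        pct_checkable = if (is.na(ck)) NA_real_ else 100 * ck / nrow(ss),
        pct_matching = if (is.na(ck) || ck == 0L) NA_real_ else 100 * mt / ck,
        n_matching = mt, n_conflicting = cf, n_non_checkable = nc)
    }
  }
  by_block <- dplyr::bind_rows(rows)
  overall <- by_block |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_blocks = dplyr::n(),
      mean_n_haplotypes = mean(.data$n_haplotypes),
      mean_pct_fully_genotyped = mean(.data$pct_fully_genotyped),
      mean_pct_haplotyped = mean(.data$pct_haplotyped),
      pooled_pct_haplotyped = 100 * sum(.data$pct_haplotyped / 100 * .data$n) /
        sum(.data$n),
      mean_pct_checkable = mean(.data$pct_checkable),
      mean_pct_matching = mean(.data$pct_matching, na.rm = TRUE),
      total_matching = sum(.data$n_matching),
      total_conflicting = sum(.data$n_conflicting),
      total_non_checkable = sum(.data$n_non_checkable),
      .groups = "drop")
  structure(list(by_block = by_block, overall = overall),
            class = "hap_summary")
}

#' @export
print.hap_summary <- function(x, ...) {
  cat("<hap_summary>\n")
  print(x$overall)
  invisible(x)
}
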