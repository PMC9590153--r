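# Stage 3: haplotyping of unrelated material (plus any demoted full-sib
# families), seeded with haplotypes confirmed in Stage 2.

#' Haplotype unrelated material
#'
#' Runs the Stage-1 parsimony procedure over the given individuals, seeded
#' with the confirmed haplotypes. If some individuals still require
#' haplotypes below the main threshold, one extra relaxed step-b cycle is
#' run with a threshold of `max(relaxed_frac * n, relaxed_min_count)`
#' individuals; its result is accepted only if it strictly increases the
#' number of uniquely solved individuals without removing uniqueness from
#' any previously solved individual.
#'
#' @inheritParams infer_haps_nofs
#' @param confirmed Integer vector of haplotype codes confirmed so far
#'   (Stage-2 parents plus any a-priori known haplotypes).
#' @return As [infer_haps_nofs()], plus `relaxed` (logical: relaxed cycle
#'   accepted).
#' @export
haplotype_unrelated <- function(dos, ploidy, confirmed = integer(),
                                params = hap_params(), table = NULL) {
  if (ncol(dos) == 0L || all(is.na(dos))) {
    return(list(haps = sort(unique(as.integer(confirmed))),
                provenance = rep("a_priori", length(unique(confirmed))),
                assign = matrix(NA_integer_, nrow = ploidy, ncol = ncol(dos),
                                dimnames = list(NULL, colnames(dos))),
                n_unique = 0L, relaxed = FALSE))
  }
  r1 <- infer_haps_nofs(dos, ploidy, prior = confirmed, params = params,
                        table = table)
  r1$relaxed <- FALSE
  if (!any(r1$unexplained)) return(r1)

  n_use <- sum(r1$usable)
  thr2 <- max(ceiling(params$relaxed_frac * n_use), params$relaxed_min_count)
  sols <- r1$groups$sols
  members <- r1$groups$members
  req <- vector("list", length(sols))
  for (i in seq_along(sols)) {
    mns <- mns_from_sols(sols[[i]], r1$haps)
    req[[i]] <- if (attr(mns, "n_new") > 0L)
      setdiff(forced_from_sols(mns), r1$haps) else integer(0)
  }
  w <- vapply(members, length, integer(1L))
  cnt <- code_counts(req, w)
  add <- sort(cnt$code[cnt$n >= thr2])
  if (length(add) == 0L) return(r1)

  known2 <- sort(unique(c(r1$haps, add)))
  asn2 <- assign_unique(dos, sols, members, known2, ploidy)
  prev <- colnames(dos)[!is.na(r1$assign[1L, ])]
  now <- colnames(dos)[!is.na(asn2$mat[1L, ])]
  if (asn2$n_unique > r1$n_unique && all(prev %in% now)) {
    prov <- c(r1$provenance, rep("parsimony", length(setdiff(known2, r1$haps))))
    ord <- order(known2)
    return(list(haps = known2,
                provenance = prov[match(known2, c(r1$haps, setdiff(known2, r1$haps)))],
                assign = asn2$mat, n_unique = asn2$n_unique,
                usable = r1$usable, unexplained = r1$unexplained,
                groups = r1$groups, relaxed = TRUE))
  }
  r1
}
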