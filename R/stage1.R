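# Stage 1: parsimonious inventory of haplotypes present in the population,
# from dosage data alone.

#' Haplotypes forced by one individual's marker dosages
#'
#' A haplotype is forced when every haplotype combination compatible with
#' the dosage vector contains it. Homozygous individuals (all dosages 0 or
#' ploidy) force one haplotype; a single intermediate dosage forces two.
#'
#' @inheritParams enumerate_hapcombs
#' @return Sorted integer vector of forced haplotype codes (possibly empty).
#' @examples
#' forced_haps(c(2, 0), 4) # c(0, 1)
#' forced_haps(c(1, 1), 2) # integer(0): the two solutions are disjoint
#' @export
forced_haps <- function(g, ploidy, table = NULL) {
  if (all(is.na(g))) stop("at least one non-missing dosage required",
                          call. = FALSE)
  sols <- enumerate_hapcombs(g, ploidy, table)
  forced_from_sols(sols)
}

forced_from_sols <- function(sols) {
  ns <- ncol(sols)
  if (ns == 0L) stop("internal error: dosage vector has no solutions",
                     call. = FALSE)
  # a code is forced iff it occurs in every column
  first <- unique(sols[, 1L])
  keep <- vapply(first, function(code) {
    all(colSums(sols == code) > 0L)
  }, logical(1L))
  sort(first[keep])
}

#' Solutions introducing the fewest haplotypes outside a known set
#'
#' @inheritParams enumerate_hapcombs
#' @param known Integer vector of haplotype codes already known to be
#'   present.
#' @return `ploidy x n` matrix of the compatible combinations whose number
#'   of distinct codes outside `known` is minimal, in lexicographic order,
#'   with attribute `n_new` giving that minimal count.
#' @export
min_new_solutions <- function(g, known, ploidy, table = NULL) {
  sols <- enumerate_hapcombs(g, ploidy, table)
  mns_from_sols(sols, known)
}

mns_from_sols <- function(sols, known) {
  ploidy <- nrow(sols)
  isnew <- matrix(!(sols %in% known), nrow = ploidy)
  # count distinct new codes per column
  nnew <- vapply(seq_len(ncol(sols)), function(i) {
    length(unique(sols[isnew[, i], i]))
  }, integer(1L))
  mn <- min(nnew)
  out <- sols[, nnew == mn, drop = FALSE]
  attr(out, "n_new") <- mn
  out
}

# group columns of a dosage matrix by identical dosage pattern (NAs
# significant); returns list(pattern = list of int vectors with NA,
# members = list of column indices)
dosage_groups <- function(dos) {
  keys <- apply(dos, 2L, function(col) paste(col, collapse = ","))
  idx <- split(seq_len(ncol(dos)), keys)
  pats <- lapply(idx, function(i) dos[, i[1L]])
  list(pattern = pats, members = idx)
}

#' Stage 1: infer a parsimonious haplotype inventory without family data
#'
#' Two-step parsimony pass over all individuals of one haploblock.
#' Step a adds haplotypes forced by at least `min_frac` of the usable
#' individuals (plus any a-priori known haplotypes, which bypass the
#' threshold). Step b repeatedly finds, per individual not yet explained,
#' the solutions introducing the fewest unknown haplotypes, and adds the
#' haplotypes required by all those minimal solutions in at least
#' `min_frac` of the individuals; iteration stops at a fixpoint. If the
#' iteration cycles instead of converging, the result of the first step-b
#' execution is used. An individual is assigned a haplotype combination
#' only when exactly one of its solutions uses known haplotypes only.
#'
#' @param dos Integer dosage matrix for one block: markers x individuals,
#'   entries in `[0, ploidy]` or `NA`; column names are individual ids.
#' @param ploidy Even ploidy level.
#' @param prior Integer vector of a-priori known haplotype codes.
#' @param params A [hap_params()] list.
#' @param table Optional `hapcomb_table` for this block size.
#' @return List with `haps` (sorted inventory codes), `provenance`
#'   (character, one of `a_priori`/`forced`/`parsimony` per code),
#'   `assign` (`ploidy x n` matrix, `NA` columns for unassigned
#'   individuals), `n_unique` (number of assigned individuals), `usable`
#'   (logical per individual), and `unexplained` (logical per individual:
#'   some minimal solution still requires unknown haplotypes).
#' @export
infer_haps_nofs <- function(dos, ploidy, prior = integer(),
                            params = hap_params(), table = NULL) {
  stopifnot(is.matrix(dos), ncol(dos) >= 1L)
  ploidy <- check_ploidy(ploidy)
  prior <- sort(unique(as.integer(prior)))
  usable <- colSums(!is.na(dos)) > 0L
  n_use <- sum(usable)
  if (n_use == 0L) stop("no individual has any non-missing dosage",
                        call. = FALSE)
  thr <- ceiling(params$min_frac * n_use)

  grp <- dosage_groups(dos[, usable, drop = FALSE])
  # translate member indices back to original columns
  orig <- which(usable)
  members <- lapply(grp$members, function(i) orig[i])
  sols <- lapply(grp$pattern, enumerate_hapcombs, ploidy = ploidy,
                 table = table)
  w <- vapply(members, length, integer(1L))

  # step a: forced haplotypes weighted by individual counts
  forced <- lapply(sols, forced_from_sols)
  cnt_a <- code_counts(forced, w)
  known_a <- sort(unique(c(prior, cnt_a$code[cnt_a$n >= thr])))

  step_b <- function(known, thr_b) {
    req <- vector("list", length(sols))
    for (i in seq_along(sols)) {
      mns <- mns_from_sols(sols[[i]], known)
      if (attr(mns, "n_new") > 0L) {
        new_forced <- setdiff(forced_from_sols(mns), known)
        req[[i]] <- new_forced
      } else req[[i]] <- integer(0)
    }
    cnt <- code_counts(req, w)
    sort(cnt$code[cnt$n >= thr_b])
  }

  known <- known_a
  first_b <- NULL
  seen <- character(0)
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    known_next <- sort(unique(c(known_a, step_b(known, thr))))
    if (iter == 1L) first_b <- known_next
    if (identical(known_next, known)) { converged <- TRUE; break }
    sig <- paste(known_next, collapse = ",")
    if (sig %in% seen) { known <- first_b; break }
    seen <- c(seen, paste(known, collapse = ","))
    known <- known_next
  }
  if (!converged && !identical(known, first_b)) known <- first_b

  asn <- assign_unique(dos, sols, members, known, ploidy)
  prov <- ifelse(known %in% prior, "a_priori",
                 ifelse(known %in% known_a, "forced", "parsimony"))
  unexpl <- rep(FALSE, ncol(dos))
  for (i in seq_along(sols)) {
    mns <- mns_from_sols(sols[[i]], known)
    if (attr(mns, "n_new") > 0L) unexpl[members[[i]]] <- TRUE
  }
  list(haps = known, provenance = prov, assign = asn$mat,
       n_unique = asn$n_unique, usable = usable, unexplained = unexpl,
       groups = list(sols = sols, members = members))
}

# count individuals contributing each code (each individual contributes a
# code at most once); x = list of code vectors, w = weights
code_counts <- function(x, w) {
  codes <- unlist(x, use.names = FALSE)
  if (length(codes) == 0L) return(list(code = integer(0), n = integer(0)))
  wts <- rep(w, lengths(x))
  agg <- rowsum(wts, codes)
  list(code = as.integer(rownames(agg)), n = as.integer(agg[, 1L]))
}

# assign individuals whose dosages have exactly one all-known solution
assign_unique <- function(dos, sols, members, known, ploidy) {
  mat <- matrix(NA_integer_, nrow = ploidy, ncol = ncol(dos),
                dimnames = list(NULL, colnames(dos)))
  n_unique <- 0L
  for (i in seq_along(sols)) {
    s <- sols[[i]]
    allknown <- which(colSums(matrix(!(s %in% known), nrow = ploidy)) == 0L)
    if (length(allknown) == 1L) {
      mat[, members[[i]]] <- s[, allknown]
      n_unique <- n_unique + length(members[[i]])
    }
  }
  list(mat = mat, n_unique = n_unique)
}
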