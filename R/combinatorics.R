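#' Number of possible haplotypes in a haploblock
#'
#' A haploblock of `nmrk` bi-allelic markers admits `2^nmrk` distinct
#' haplotypes (binary allele patterns). Haplotypes are encoded as integer
#' codes in `[0, 2^nmrk)`, where bit `j` (bit 0 = first marker of the block)
#' is the allele carried at marker `j + 1`.
#'
#' @param nmrk Number of bi-allelic markers in the block (1--30).
#' @return Integer: `2^nmrk`.
#' @examples
#' n_haplotypes(4) # 16
#' n_haplotypes(8) # 256
#' @export
n_haplotypes <- function(nmrk) {
  stopifnot(length(nmrk) == 1L, is.numeric(nmrk), !is.na(nmrk),
            nmrk >= 1, nmrk <= 30)
  as.integer(2^nmrk)
}

#' Decode haplotype codes into per-marker alleles
#'
#' @param code Integer haplotype code(s) in `[0, 2^nmrk)`.
#' @param nmrk Number of markers in the block.
#' @return For a single code, an integer vector of length `nmrk` of 0/1
#'   alleles; for several codes, an `nmrk x length(code)` matrix.
#' @examples
#' haplotype_alleles(5, 3) # c(1, 0, 1)
#' @export
haplotype_alleles <- function(code, nmrk) {
  nhap <- n_haplotypes(nmrk)
  code <- as.integer(code)
  if (length(code) == 0L || anyNA(code) || any(code < 0L) || any(code >= nhap)) {
    stop("haplotype code must be in [0, ", nhap, ")", call. = FALSE)
  }
  a <- vapply(0:(nmrk - 1L),
              function(j) bitwAnd(bitwShiftR(code, j), 1L),
              integer(length(code)))
  if (length(code) == 1L) as.integer(a) else t(a)
}

# nmrk x nhap matrix of alleles; column code+1 holds the bits of `code`.
allele_matrix <- function(nmrk) {
  nhap <- 2L^nmrk
  codes <- 0:(nhap - 1L)
  t(vapply(0:(nmrk - 1L),
           function(j) bitwAnd(bitwShiftR(codes, j), 1L),
           integer(nhap)))
}

#' Marker dosages produced by a haplotype combination
#'
#' The dosage of marker `j` is the number of haplotypes in the combination
#' carrying allele 1 at that marker; dosages always sum over haplotypes, so
#' a combination of `ploidy` haplotypes yields dosages in `[0, ploidy]`.
#'
#' @param hc A haplotype combination: sorted integer vector of codes (one
#'   combination), or a `ploidy x n` matrix (one combination per column).
#' @param nmrk Number of markers in the block.
#' @return Integer dosage vector of length `nmrk`, or an `nmrk x n` matrix.
#' @examples
#' mrkdos_of_hapcomb(c(3, 3, 1, 0), 2) # c(3, 2)
#' @export
mrkdos_of_hapcomb <- function(hc, nmrk) {
  A <- allele_matrix(nmrk)
  if (is.matrix(hc)) {
    d <- A[, hc[1L, ] + 1L, drop = FALSE]
    for (r in seq_len(nrow(hc))[-1L]) {
      d <- d + A[, hc[r, ] + 1L, drop = FALSE]
    }
    dimnames(d) <- NULL
    d
  } else {
    as.integer(rowSums(A[, hc + 1L, drop = FALSE]))
  }
}

#' Mixed-radix index of a fully observed marker dosage vector
#'
#' Bijective key used to index the precomputed haplotype-combination tables:
#' `sum(g[j] * (ploidy+1)^(j-1))`.
#'
#' @param g Integer dosage vector (no missing values), entries in
#'   `[0, ploidy]`.
#' @param ploidy Even ploidy level.
#' @return Integer index in `[0, (ploidy+1)^length(g))`.
#' @examples
#' gmrk_index(c(1, 2), 4) # 11
#' @export
gmrk_index <- function(g, ploidy) {
  g <- as.integer(g)
  if (anyNA(g)) stop("gmrk_index requires a fully observed dosage vector",
                     call. = FALSE)
  if (any(g < 0L | g > ploidy)) {
    stop("dosages must be in [0, ploidy]", call. = FALSE)
  }
  as.integer(sum(g * (ploidy + 1)^(seq_along(g) - 1L)))
}

# vectorized keys for an nmrk x n dosage matrix (no NAs)
gmrk_keys <- function(dos, ploidy) {
  pw <- (ploidy + 1)^(seq_len(nrow(dos)) - 1L)
  as.integer(round(colSums(dos * pw)))
}

# decode keys -> nmrk x n dosage matrix
gmrk_unkey <- function(key, nmrk, ploidy) {
  b <- ploidy + 1L
  d <- matrix(0L, nrow = nmrk, ncol = length(key))
  k <- as.integer(key)
  for (m in seq_len(nmrk)) {
    d[m, ] <- k %% b
    k <- k %/% b
  }
  d
}

#' Total number of haplotype combinations for a block
#'
#' Number of multisets of `ploidy` haplotypes drawn from the `2^nmrk`
#' possible haplotypes: `choose(2^nmrk + ploidy - 1, ploidy)`.
#'
#' @inheritParams n_haplotypes
#' @param ploidy Even ploidy level.
#' @return Numeric count (may exceed the integer range for large blocks).
#' @examples
#' count_all_hapcombs(2, 4) # 35
#' @export
count_all_hapcombs <- function(nmrk, ploidy) {
  check_ploidy(ploidy)
  choose(2^nmrk + ploidy - 1, ploidy)
}

check_ploidy <- function(ploidy) {
  stopifnot(length(ploidy) == 1L, is.numeric(ploidy), !is.na(ploidy))
  if (ploidy < 2 || ploidy %% 2 != 0) {
    stop("ploidy must be an even integer >= 2", call. = FALSE)
  }
  invisible(as.integer(ploidy))
}

#' Default haploblock size limit for the combination tables
#'
#' Precomputed combination tables are capped by default at 8 markers for
#' tetraploids and 6 for hexaploids (beyond that the tables no longer fit
#' in memory comfortably); diploids allow up to 10, higher ploidies 4.
#'
#' @param ploidy Even ploidy level.
#' @return Integer marker limit.
#' @export
default_max_nmrk <- function(ploidy) {
  ploidy <- check_ploidy(ploidy)
  switch(as.character(ploidy), "2" = 10L, "4" = 8L, "6" = 6L, 4L)
}

# all nondecreasing k-tuples (multisets) over codes 0..nhap-1, in
# lexicographic column order, as a k x N integer matrix
enum_multisets <- function(k, nhap) {
  if (k == 1L) return(matrix(0:(nhap - 1L), nrow = 1L))
  cm <- utils::combn(nhap + k - 1L, k)
  cm - seq_len(k)
}

# join two lex-ordered half-multiset matrices into full multisets with
# max(left) <= min(right); output columns remain in lexicographic order
join_all_multisets <- function(left, right) {
  lmax <- left[nrow(left), ]
  rmin <- right[1L, ]
  pos <- findInterval(lmax - 0.5, rmin)
  ncand <- ncol(right) - pos
  keep <- which(ncand > 0L)
  idx1 <- rep(keep, ncand[keep])
  idx2 <- sequence(ncand[keep], from = pos[keep] + 1L)
  rbind(left[, idx1, drop = FALSE], right[, idx2, drop = FALSE])
}

#' Build the haplotype-combination lookup table for a block size
#'
#' Tabulates, for every fully observed marker dosage vector of a block of
#' `nmrk` markers at the given ploidy, all haplotype combinations that
#' produce it. Tabulating in advance makes repeated lookups during
#' haplotyping essentially free; the table for a `(nmrk, ploidy)` pair is
#' reusable across blocks and runs.
#'
#' @inheritParams count_all_hapcombs
#' @param max_nmrk Capacity limit; requests beyond it are refused with an
#'   error of class `haplodose_capacity_error`.
#' @return An object of class `hapcomb_table`: all
#'   `choose(2^nmrk+ploidy-1, ploidy)` combinations stored column-wise,
#'   sorted by dosage key and lexicographically within key, with an index
#'   over all `(ploidy+1)^nmrk` keys.
#' @examples
#' tbl <- build_hapcomb_table(2, 2)
#' tbl$count # 10
#' @export
build_hapcomb_table <- function(nmrk, ploidy, max_nmrk = default_max_nmrk(ploidy)) {
  ploidy <- check_ploidy(ploidy)
  stopifnot(length(nmrk) == 1L, is.numeric(nmrk), nmrk >= 1)
  nmrk <- as.integer(nmrk)
  if (nmrk > max_nmrk) {
    stop(structure(
      class = c("haplodose_capacity_error", "error", "condition"),
      list(message = sprintf(
             "combination table for %d markers at ploidy %d exceeds the capacity limit (%d markers)",
             nmrk, ploidy, as.integer(max_nmrk)),
           call = NULL)))
  }
  nhap <- 2L^nmrk
  half <- enum_multisets(ploidy %/% 2L, nhap)
  combs <- join_all_multisets(half, half)
  dos <- mrkdos_of_hapcomb(combs, nmrk)
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = nmrk)
  key <- gmrk_keys(dos, ploidy)
  ord <- do.call(order, c(list(key),
                          lapply(seq_len(ploidy), function(r) combs[r, ])))
  combs <- combs[, ord, drop = FALSE]
  key <- key[ord]
  nkeys <- as.integer((ploidy + 1)^nmrk)
  counts <- tabulate(key + 1L, nbins = nkeys)
  structure(list(format_version = 1L, nmrk = nmrk, ploidy = ploidy,
                 nhap = nhap, count = ncol(combs), combs = combs, key = key,
                 counts = counts, start = c(0L, cumsum(counts))),
            class = "hapcomb_table")
}

#' @export
print.hapcomb_table <- function(x, ...) {
  cat(sprintf("<hapcomb_table> %d markers, ploidy %d: %d combinations over %d dosage keys\n",
              x$nmrk, x$ploidy, x$count, length(x$counts)))
  invisible(x)
}

#' Persist / reload a haplotype-combination table
#'
#' The table is written as a versioned serialized container; rebuilding and
#' rewriting with the same format version is byte-identical.
#'
#' @param table A `hapcomb_table`.
#' @param path File path.
#' @return `write_hapcomb_table` returns `path` invisibly;
#'   `read_hapcomb_table` returns the table.
#' @export
write_hapcomb_table <- function(table, path) {
  stopifnot(inherits(table, "hapcomb_table"))
  saveRDS(table, path, version = 3L, compress = "gzip")
  invisible(path)
}

#' @rdname write_hapcomb_table
#' @export
read_hapcomb_table <- function(path) {
  tbl <- readRDS(path)
  if (!inherits(tbl, "hapcomb_table") || !identical(tbl$format_version, 1L)) {
    stop("not a valid haplotype-combination table (format version 1)",
         call. = FALSE)
  }
  if (tbl$count != count_all_hapcombs(tbl$nmrk, tbl$ploidy)) {
    stop("corrupt haplotype-combination table: count mismatch", call. = FALSE)
  }
  tbl
}

# in-session table cache
.hap_cache <- new.env(parent = emptyenv())

#' Get (and cache) the combination table for a block size
#'
#' @inheritParams build_hapcomb_table
#' @param build Build the table if not cached yet (otherwise return `NULL`).
#' @return A `hapcomb_table` or `NULL`.
#' @export
get_hapcomb_table <- function(nmrk, ploidy, max_nmrk = default_max_nmrk(ploidy),
                              build = TRUE) {
  key <- paste0("t", nmrk, "x", ploidy)
  tbl <- .hap_cache[[key]]
  if (!is.null(tbl)) return(tbl)
  if (!build) return(NULL)
  tbl <- build_hapcomb_table(nmrk, ploidy, max_nmrk)
  assign(key, tbl, envir = .hap_cache)
  tbl
}

table_lookup <- function(tbl, key) {
  s <- tbl$start[key + 1L]
  n <- tbl$counts[key + 1L]
  tbl$combs[, s + seq_len(n), drop = FALSE]
}

#' Enumerate all haplotype combinations compatible with a dosage vector
#'
#' Returns exactly the combinations of `ploidy` haplotypes whose per-marker
#' dosages match `g` at every non-missing position. Missing markers (`NA`)
#' are unconstrained, so masking a dosage can only enlarge the solution set.
#'
#' @param g Integer dosage vector for one block (length = number of
#'   markers); `NA` marks a missing dosage.
#' @param ploidy Even ploidy level.
#' @param table Optional precomputed `hapcomb_table` for this block size
#'   (used for fast lookup). If `NULL`, a cached table is used when
#'   available and a direct meet-in-the-middle enumeration otherwise.
#' @return `ploidy x n` integer matrix; each column a sorted haplotype
#'   combination; columns in lexicographic order.
#' @examples
#' enumerate_hapcombs(c(1, 1), 2) # two solutions: {0,3} and {1,2}
#' @export
enumerate_hapcombs <- function(g, ploidy, table = NULL) {
  ploidy <- check_ploidy(ploidy)
  nmrk <- length(g)
  stopifnot(nmrk >= 1L)
  g <- suppressWarnings(as.integer(g))
  obs <- !is.na(g)
  if (any(g[obs] < 0L | g[obs] > ploidy)) {
    stop("dosages must be in [0, ploidy] or NA", call. = FALSE)
  }
  if (is.null(table)) {
    table <- get_hapcomb_table(nmrk, ploidy, build = FALSE)
  } else {
    stopifnot(inherits(table, "hapcomb_table"),
              table$nmrk == nmrk, table$ploidy == ploidy)
  }
  if (!is.null(table)) {
    if (all(obs)) return(table_lookup(table, gmrk_index(g, ploidy)))
    miss <- which(!obs)
    grid <- as.matrix(expand.grid(rep(list(0:ploidy), length(miss)),
                                  KEEP.OUT.ATTRS = FALSE))
    pw <- (ploidy + 1)^(seq_len(nmrk) - 1L)
    base <- sum(g[obs] * pw[obs])
    keys <- as.integer(base + as.vector(grid %*% pw[miss]))
    res <- do.call(cbind, lapply(keys, table_lookup, tbl = table))
    ord <- do.call(order, lapply(seq_len(ploidy), function(r) res[r, ]))
    return(res[, ord, drop = FALSE])
  }
  enum_hapcombs_direct(g, ploidy)
}

# meet-in-the-middle enumeration for a single dosage vector, no full table
enum_hapcombs_direct <- function(g, ploidy) {
  nmrk <- length(g)
  nhap <- 2L^nmrk
  k <- ploidy %/% 2L
  H <- enum_multisets(k, nhap)
  dosH <- mrkdos_of_hapcomb(H, nmrk)
  if (!is.matrix(dosH)) dosH <- matrix(dosH, nrow = nmrk)
  obs <- which(!is.na(g))
  pw <- (ploidy + 1)^(seq_along(obs) - 1L)
  keyH <- if (length(obs)) as.integer(round(colSums(dosH[obs, , drop = FALSE] * pw)))
          else integer(ncol(H)) * 0L
  rmin <- H[1L, ]
  comp <- keyH * (nhap + 1) + rmin            # composite sort key
  ordR <- order(comp)
  compS <- comp[ordR]
  HS <- H[, ordR, drop = FALSE]
  # left halves: required complement key
  need <- matrix(g[obs], nrow = length(obs), ncol = ncol(H)) -
    dosH[obs, , drop = FALSE]
  valid <- colSums(need < 0L | need > k) == 0L
  if (length(obs) == 0L) valid <- rep(TRUE, ncol(H))
  needkey <- if (length(obs)) as.integer(round(colSums(need * pw))) else integer(ncol(H))
  lmax <- H[k, ]
  lo <- findInterval(needkey * (nhap + 1) + lmax - 0.5, compS) + 1L
  hi <- findInterval(needkey * (nhap + 1) + nhap, compS)
  n_i <- pmax(hi - lo + 1L, 0L) * valid
  keep <- which(n_i > 0L)
  if (length(keep) == 0L) {
    return(matrix(integer(0), nrow = ploidy, ncol = 0L))
  }
  idx1 <- rep(keep, n_i[keep])
  idx2 <- sequence(n_i[keep], from = lo[keep])
  res <- rbind(H[, idx1, drop = FALSE], HS[, idx2, drop = FALSE])
  ord <- do.call(order, lapply(seq_len(ploidy), function(r) res[r, ]))
  res[, ord, drop = FALSE]
}

# string form of a haplotype combination (used in result tables)
hapcomb_chr <- function(hc) paste(hc, collapse = "+")
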