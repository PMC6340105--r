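#' Build and validate a pedigree
#'
#' Takes raw (animal, sire, dam) triplets, checks identifiers, and returns a
#' topologically sorted pedigree in which every parent precedes its offspring.
#' Unknown parents (coded `0`, `NA` or the empty string) are treated as
#' unrelated founders.
#'
#' @param records A data frame (or matrix) whose first three columns are
#'   animal, sire and dam identifiers. Identifiers are treated as opaque
#'   tokens; `0`, `""` and `NA` mean "unknown parent".
#' @return An object of class `"pedigree"`: a data frame with columns `id`,
#'   `sire`, `dam` (character; `NA` = unknown) and integer columns
#'   `sire_idx`, `dam_idx` (0 = unknown) giving parent positions in the
#'   sorted order.
#' @examples
#' ped <- build_pedigree(data.frame(id = c("o", "s", "d"),
#'                                  sire = c("s", 0, 0),
#'                                  dam  = c("d", 0, 0)))
#' ped$id  # parents first
#' @export
build_pedigree <- function(records) {
  records <- as.data.frame(records)
  if (ncol(records) < 3L)
    stop("pedigree records need three columns: animal, sire, dam")
  id   <- trimws(as.character(records[[1L]]))
  sire <- trimws(as.character(records[[2L]]))
  dam  <- trimws(as.character(records[[3L]]))
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)]   <- NA_character_
  if (anyNA(id) || any(id == ""))
    stop("missing animal identifier in pedigree")
  if (anyDuplicated(id))
    stop("duplicate pedigree id: ", id[duplicated(id)][1L])
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("cycle: animal ", id[self[1L]], " is its own parent")

  ## parents that never appear as animals become founders prepended in place
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {
    id   <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam  <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(id)
  pos <- match(id, id)  # identity; we need lookup by name below
  si <- match(sire, id); si[is.na(si)] <- 0L
  di <- match(dam, id);  di[is.na(di)] <- 0L

  ## Kahn's algorithm: edges parent -> offspring
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(si[j], di[j])) if (p > 0L) {
      indeg[j] <- indeg[j] + 1L
      kids[[p]] <- c(kids[[p]], j)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    bad <- id[setdiff(seq_len(n), order)][1L]
    stop("cycle detected in pedigree involving animal ", bad)
  }
  id <- id[order]; sire <- sire[order]; dam <- dam[order]
  out <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  out$sire_idx <- match(out$sire, out$id); out$sire_idx[is.na(out$sire_idx)] <- 0L
  out$dam_idx  <- match(out$dam,  out$id); out$dam_idx[is.na(out$dam_idx)]  <- 0L
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree file
#'
#' Whitespace- or comma-separated triplets `animal sire dam`, `0` = unknown
#' parent, optional header line.
#'
#' @param path File path.
#' @param header Logical; does the file start with a header line?
#' @return A [build_pedigree()] object.
#' @export
read_pedigree <- function(path, header = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  build_pedigree(utils::read.table(path, header = header, sep = sep,
                                   colClasses = "character"))
}

#' Inbreeding coefficients (Meuwissen--Luo)
#'
#' @param ped A sorted [build_pedigree()] pedigree.
#' @return Numeric vector of inbreeding coefficients F, one per animal in
#'   pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  meuwissen_luo_f(ped$sire_idx, ped$dam_idx)
}

#' Additive (numerator) relationship matrix
#'
#' Tabular method: founders are unrelated and non-inbred; for animal `i` with
#' parents `s`, `d`, `a_ij = (a_sj + a_dj)/2` for older `j` and
#' `a_ii = 1 + a_sd/2`, so the diagonal carries `1 + F`.
#'
#' @param ped A sorted [build_pedigree()] pedigree.
#' @return A dense symmetric matrix with dimnames equal to the pedigree ids.
#'   Dense storage: intended for pedigrees up to a few thousand animals.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  A <- tabular_a_matrix(ped$sire_idx, ped$dam_idx)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: Mendelian sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (3/4 or 1 with one or both parents unknown)
#' feed the usual `1/d_i` contributions to animal and parent equations.
#' Inbreeding coefficients come from the Meuwissen--Luo algorithm, so the
#' result is the exact inverse of [relationship_matrix()].
#'
#' @param ped A sorted [build_pedigree()] pedigree.
#' @return A sparse symmetric `Matrix::dgCMatrix` with pedigree ids as
#'   dimnames.
#' @export
inverse_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  f <- inbreeding(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  fs <- rep(-1, n)  # unknown parent contributes F = -1,
  fd <- rep(-1, n)  # so that d covers the 3/4 and 1 cases
  fs[si > 0L] <- f[si[si > 0L]]
  fd[di > 0L] <- f[di[di > 0L]]
  d <- 0.5 - 0.25 * (fs + fd)
  # vectorised triplet assembly
  w <- 1 / d
  ii <- c(seq_len(n)); jj <- c(seq_len(n)); xx <- w
  par <- cbind(si, di)
  for (k in 1:2) {
    p <- par[, k]
    has <- p > 0L
    if (any(has)) {
      i <- which(has)
      ii <- c(ii, i, p[i], p[i])
      jj <- c(jj, p[i], i, p[i])
      xx <- c(xx, -0.5 * w[i], -0.5 * w[i], 0.25 * w[i])
    }
  }
  both <- which(si > 0L & di > 0L)
  if (length(both)) {
    ii <- c(ii, si[both], di[both])
    jj <- c(jj, di[both], si[both])
    xx <- c(xx, 0.25 * w[both], 0.25 * w[both])
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Ainv, "generalMatrix")
}

#' Mean within-group additive relationship
#'
#' Mean of `a_ij` over unordered pairs `i != j` within each group (pen) and
#' pooled over all within-group pairs. Groups of size 1 are excluded with a
#' warning.
#'
#' @param A Relationship matrix (dense, with id dimnames) from
#'   [relationship_matrix()].
#' @param groups Named character/factor vector mapping animal id to group, or
#'   a data frame with columns `id` and `pen`.
#' @return List with `pooled` (scalar mean over all within-group pairs) and
#'   `per_group` (named vector).
#' @export
mean_within_group_relationship <- function(A, groups) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups$pen), groups$id)
  } else {
    g <- stats::setNames(as.character(groups), names(groups))
  }
  if (is.null(names(g))) stop("groups must be named by animal id")
  miss <- setdiff(names(g), rownames(A))
  if (length(miss)) stop("animals not in relationship matrix: ", miss[1L])
  per <- c(); tot_s <- 0; tot_n <- 0
  for (p in unique(g)) {
    ids <- names(g)[g == p]
    if (length(ids) < 2L) {
      warning("group ", p, " has a single animal; excluded")
      next
    }
    sub <- A[ids, ids, drop = FALSE]
    s <- (sum(sub) - sum(diag(sub))) / 2
    np <- length(ids) * (length(ids) - 1L) / 2
    per[p] <- s / np
    tot_s <- tot_s + s; tot_n <- tot_n + np
  }
  if (tot_n == 0) stop("no group with at least two animals")
  list(pooled = tot_s / tot_n, per_group = per)
}
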