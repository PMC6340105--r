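#' Read electronic feeder visit records
#'
#' Expects a CSV with header `animal,pen,start_iso8601,duration_min,intake_g`.
#'
#' @param path File path.
#' @return Data frame with columns `animal`, `pen`, `start` (POSIXct,
#'   timezone-naive, parsed as UTC), `duration_min`, `intake_g`.
#' @export
read_feeder_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[1:5] <- c("animal", "pen", "start", "duration_min", "intake_g")
  d$start <- as.POSIXct(d$start, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS"))
  d
}

#' Derive daily feeding behaviour traits from feeder visits
#'
#' Visits are bucketed into 1-hour blocks; consecutive visits of the same
#' animal that fall in the same hour block with a gap below `merge_gap_min`
#' minutes are merged into a single feeding event (the usual editing of
#' single-space feeder data, where sub-minute re-entries are hardware
#' artefacts, not new visits). Daily traits are then: FF, the number of
#' visits; OT, total trough occupation (min/day); FR, total intake divided by
#' OT (g/min, undefined when OT = 0); FInt, the mean gap between the end of a
#' visit and the start of the next within the day (min, undefined with fewer
#' than 2 visits). Gaps spanning midnight are never counted.
#'
#' @param visits Data frame with columns `animal`, `pen`, `start` (POSIXct),
#'   `duration_min` (> 0), `intake_g` (>= 0). Records violating the sign
#'   constraints are dropped with a message.
#' @param merge_gap_min Merge threshold in minutes (default 1).
#' @return Data frame with one row per animal-day: `animal`, `pen`, `day`
#'   (Date), `FF`, `OT`, `FR`, `FInt`.
#' @export
derive_daily_traits <- function(visits, merge_gap_min = 1) {
  v <- as.data.frame(visits)
  bad <- v$duration_min <= 0 | v$intake_g < 0 | is.na(v$duration_min) |
    is.na(v$intake_g)
  if (any(bad)) {
    message("dropping ", sum(bad), " feeder record(s) with non-positive ",
            "duration or negative intake")
    v <- v[!bad, , drop = FALSE]
  }
  if (!nrow(v)) stop("no valid feeder visits")
  v <- v[order(v$animal, v$start), , drop = FALSE]
  v$day <- as.Date(v$start, tz = "UTC")
  v$end <- v$start + v$duration_min * 60

  # merge sub-threshold re-entries within the same hour block
  i <- 2L
  while (i <= nrow(v)) {
    same <- v$animal[i] == v$animal[i - 1L] && v$day[i] == v$day[i - 1L]
    if (same) {
      gap <- as.numeric(difftime(v$start[i], v$end[i - 1L], units = "mins"))
      same_block <- format(v$start[i], "%H") == format(v$start[i - 1L], "%H")
      if (gap < merge_gap_min && same_block) {
        v$end[i - 1L] <- max(v$end[i - 1L], v$end[i])
        v$duration_min[i - 1L] <- v$duration_min[i - 1L] + v$duration_min[i]
        v$intake_g[i - 1L] <- v$intake_g[i - 1L] + v$intake_g[i]
        v <- v[-i, , drop = FALSE]
        next
      }
    }
    i <- i + 1L
  }

  sp <- split(v, list(v$animal, v$day), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ot <- sum(d$duration_min)
    fint <- if (nrow(d) >= 2L) {
      mean(as.numeric(difftime(d$start[-1L], d$end[-nrow(d)],
                               units = "mins")))
    } else NA_real_
    data.frame(animal = d$animal[1L], pen = d$pen[1L], day = d$day[1L],
               FF = nrow(d), OT = ot,
               FR = if (ot > 0) sum(d$intake_g) / ot else NA_real_,
               FInt = fint, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$animal, out$day), , drop = FALSE]
}

#' Aggregate daily behaviour traits into period or whole-test means
#'
#' @param daily Output of [derive_daily_traits()] (or any data frame with
#'   `animal`, `day`, `FF`, `OT`, `FR`, `FInt`).
#' @param window `"overall"` for one record per animal, or `"period"` for
#'   consecutive periods of `period_days` days counted from the first day in
#'   the data.
#' @param period_days Period length in days (default 14).
#' @return Data frame `animal`, `period` (0 for overall), per-trait means of
#'   the defined daily values, and `days` observed. Animals absent in a
#'   window are simply absent from the output.
#' @export
aggregate_traits <- function(daily, window = c("overall", "period"),
                             period_days = 14) {
  window <- match.arg(window)
  d <- as.data.frame(daily)
  d$period <- if (window == "overall") 0L else
    as.integer(floor(as.numeric(d$day - min(d$day)) / period_days)) + 1L
  sp <- split(d, list(d$animal, d$period), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(x) {
    data.frame(animal = x$animal[1L], period = x$period[1L],
               FR = mean(x$FR, na.rm = TRUE), FF = mean(x$FF, na.rm = TRUE),
               OT = mean(x$OT, na.rm = TRUE),
               FInt = if (all(is.na(x$FInt))) NA_real_ else
                 mean(x$FInt, na.rm = TRUE),
               days = nrow(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$animal, out$period), , drop = FALSE]
}

#' Phenotypic correlations among behaviour traits (and growth)
#'
#' Pearson correlations over animals with complete records.
#'
#' @param traits Data frame with column `animal` plus numeric trait columns.
#' @param adg Optional named numeric vector (or data.frame `animal`,`adg`)
#'   of average daily gain to append.
#' @return Correlation matrix. Zero-variance columns give `NA` rows/columns
#'   with a warning.
#' @export
phenotypic_correlations <- function(traits, adg = NULL) {
  m <- as.data.frame(traits)
  if (!is.null(adg)) {
    if (is.data.frame(adg)) adg <- stats::setNames(adg[[2L]], adg[[1L]])
    m$ADG <- as.numeric(adg[as.character(m$animal)])
  }
  num <- m[vapply(m, is.numeric, TRUE)]
  num$period <- NULL; num$days <- NULL
  cc <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(cc) < 3L) stop("need at least 3 complete cases")
  sds <- vapply(cc, stats::sd, 0)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(names(sds)[sds == 0], collapse = ", "),
            "; correlations undefined")
  suppressWarnings(stats::cor(cc))
}

#' Rank stability of behaviour traits across consecutive periods
#'
#' Spearman correlation of animal ranks between each pair of consecutive
#' periods, per trait, over the animals present in both periods.
#'
#' @param period_traits Per-period output of [aggregate_traits()].
#' @param traits Trait columns to use.
#' @return Data frame `trait`, `period_pair`, `rho`, `n_shared`. Pairs with
#'   fewer than 3 shared animals give `NA` with a warning.
#' @export
rank_stability <- function(period_traits,
                           traits = c("FR", "FF", "OT", "FInt")) {
  d <- as.data.frame(period_traits)
  periods <- sort(unique(d$period))
  if (length(periods) < 2L) stop("need at least 2 periods")
  out <- list()
  for (tr in traits) {
    for (k in seq_len(length(periods) - 1L)) {
      a <- d[d$period == periods[k], c("animal", tr)]
      b <- d[d$period == periods[k + 1L], c("animal", tr)]
      shared <- intersect(a$animal, b$animal)
      rho <- if (length(shared) < 3L) {
        warning("fewer than 3 shared animals for ", tr, " periods ",
                periods[k], "-", periods[k + 1L])
        NA_real_
      } else {
        stats::cor(a[match(shared, a$animal), tr],
                   b[match(shared, b$animal), tr], method = "spearman")
      }
      out[[length(out) + 1L]] <- data.frame(
        trait = tr,
        period_pair = paste0(periods[k], "-", periods[k + 1L]),
        rho = rho, n_shared = length(shared), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Standardize a trait to z-scores
#'
#' Centred and scaled by the population (n-denominator) standard deviation,
#' computed globally over all phenotyped animals.
#'
#' @param x Numeric vector.
#' @return z-scores with mean 0 and population SD 1.
#' @export
standardize <- function(x) {
  if (anyNA(x)) stop("missing values in trait to standardize")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero standard deviation; cannot standardize")
  (x - mean(x)) / s
}

#' Euclidean distance between the standardized records of two animals
#'
#' Single trait: `|z_i - z_j|`. Several traits: root of the summed squared
#' differences.
#'
#' @param z_i,z_j Standardized trait value(s); equal length, no missing.
#' @return Scalar distance >= 0.
#' @export
pair_distance <- function(z_i, z_j) {
  if (length(z_i) != length(z_j)) stop("trait vectors differ in length")
  if (anyNA(z_i) || anyNA(z_j)) stop("missing trait component")
  sqrt(sum((z_i - z_j)^2))
}

#' Pair-specific interaction matrix over pen mates
#'
#' For the classical social animal model (`mode = "CLASSICAL"`) entries are 1
#' for animals sharing a pen and 0 otherwise. For the behaviour-based modes,
#' the Euclidean distance between the (globally standardized) behaviour
#' records of every within-pen pair is computed, and entries are the
#' standardized distances `c_ij = (d_ij - mean(d)) / sd(d)` with mean and
#' population SD taken over all within-pen pairs in the data set, so the
#' within-pen entries have mean 0 and SD 1. Cross-pen entries and the
#' diagonal are 0. Negative entries (pairs closer in behaviour than average)
#' are retained as signed interaction degrees.
#'
#' @param traits Data frame with column `animal` and behaviour trait columns
#'   (`FR`, `FF`, `OT`, `FInt`); may be `NULL` for `mode = "CLASSICAL"`.
#' @param pens Named vector mapping animal id to pen, or data frame with
#'   columns `animal` (or `id`) and `pen`.
#' @param mode One of `"CLASSICAL"`, `"FR"`, `"FF"`, `"OT"`, `"FINT"`,
#'   `"ALL"`.
#' @return An object of class `"interaction_matrix"`: list with `C` (sparse
#'   symmetric matrix with animal-id dimnames), `mode`, `pens`, and the
#'   distance standardization constants `d_mean`, `d_sd`.
#' @export
interaction_matrix <- function(traits, pens,
                               mode = c("CLASSICAL", "FR", "FF", "OT",
                                        "FINT", "ALL")) {
  mode <- match.arg(mode)
  if (is.data.frame(pens)) {
    idc <- if ("animal" %in% names(pens)) "animal" else "id"
    pens <- stats::setNames(as.character(pens$pen), pens[[idc]])
  }
  ids <- names(pens)
  if (is.null(ids)) stop("pens must be named by animal id")
  n <- length(ids)
  pen_of <- as.character(pens)
  sizes <- table(pen_of)
  if (any(sizes < 2L))
    warning("pen(s) with fewer than 2 phenotyped animals get zero rows: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))

  Z <- NULL
  if (mode != "CLASSICAL") {
    cols <- if (mode == "ALL") c("FR", "FF", "OT", "FINT") else mode
    tr_names <- c(FR = "FR", FF = "FF", OT = "OT", FINT = "FInt")
    traits <- as.data.frame(traits)
    miss <- setdiff(ids, as.character(traits$animal))
    if (length(miss))
      stop("behaviour trait missing for animal(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    rows <- match(ids, as.character(traits$animal))
    Z <- sapply(tr_names[cols], function(cl) {
      x <- traits[[cl]][rows]
      if (anyNA(x)) stop("missing ", cl, " for an animal in a non-CLASSICAL ",
                         "interaction mode")
      standardize(x)
    })
    Z <- matrix(Z, nrow = n)
  }

  ii <- jj <- integer(0); dd <- numeric(0)
  for (p in unique(pen_of)) {
    at <- which(pen_of == p)
    if (length(at) < 2L) next
    prs <- utils::combn(at, 2L)
    ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
    if (mode == "CLASSICAL") {
      dd <- c(dd, rep(1, ncol(prs)))
    } else {
      dd <- c(dd, apply(prs, 2L, function(ij)
        pair_distance(Z[ij[1L], ], Z[ij[2L], ])))
    }
  }
  d_mean <- NA_real_; d_sd <- NA_real_
  vals <- dd
  if (mode != "CLASSICAL") {
    d_mean <- mean(dd)
    d_sd <- sqrt(mean((dd - d_mean)^2))
    if (d_sd == 0) stop("all within-pen distances identical; cannot ",
                        "standardize interaction degrees")
    vals <- (dd - d_mean) / d_sd
  }
  C <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(vals, vals),
                            dims = c(n, n), dimnames = list(ids, ids))
  structure(list(C = C, mode = mode, pens = pens,
                 d_mean = d_mean, d_sd = d_sd),
            class = "interaction_matrix")
}

#' Within-pen interaction degrees
#'
#' Extracts the within-pen off-diagonal entries of an interaction matrix
#' (each unordered pair once), the empirical distribution whose quartiles the
#' degree-dependent variance partition is evaluated at.
#'
#' @param im An [interaction_matrix()] object.
#' @return Numeric vector of pair entries.
#' @export
interaction_degrees <- function(im) {
  stopifnot(inherits(im, "interaction_matrix"))
  pen_of <- as.character(im$pens)
  out <- numeric(0)
  for (p in unique(pen_of)) {
    at <- which(pen_of == p)
    if (length(at) < 2L) next
    prs <- utils::combn(at, 2L)
    out <- c(out, im$C[cbind(prs[1L, ], prs[2L, ])])
  }
  out
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix (", x$mode, " mode): ", nrow(x$C), " animals, ",
      length(unique(x$pens)), " pens\n", sep = "")
  invisible(x)
}
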