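#' Construct a plate observation
#'
#' The qualitative read-out of one spot-titer immunity assay relative to the
#' naive control host: efficiency of plating (EOP), whether plaques form, the
#' number of highest dilutions showing spots of lysis, and turbidity /
#' plaque-size relative to the control.
#'
#' @param plaques_present Logical.
#' @param eop Efficiency of plating (>= 0); required when plaques are present.
#' @param spot_titers_with_lysis Count (0-8) of highest dilutions with lysis.
#' @param turbidity,plaque_size `"reduced"`, `"equal"` or `"increased"`
#'   relative to the control infection.
#' @return Object of class `plate_observation`.
#' @export
plate_observation <- function(plaques_present, eop = NA_real_,
                              spot_titers_with_lysis = 0L,
                              turbidity = "equal", plaque_size = "equal") {
  turbidity <- match.arg(turbidity, c("reduced", "equal", "increased"))
  plaque_size <- match.arg(plaque_size, c("reduced", "equal", "increased"))
  if (plaques_present && is.na(eop))
    stop("inconsistent observation: plaques present but no EOP")
  if (!is.na(eop) && eop < 0) stop("EOP must be >= 0")
  if (spot_titers_with_lysis < 0 || spot_titers_with_lysis > 8)
    stop("spot_titers_with_lysis must be in 0..8")
  structure(list(plaques_present = plaques_present, eop = eop,
                 spot_titers_with_lysis = as.integer(spot_titers_with_lysis),
                 turbidity = turbidity, plaque_size = plaque_size),
            class = "plate_observation")
}

#' Score a plate observation on the 0-6 infection rubric
#'
#' Ordinal infection score relative to the naive host: 0 no spots of lysis or
#' plaques; 1 lysis at the highest 1-2 dilutions without plaques; 2 plaques
#' with EOP below `eop_lo` or lysis at the highest 3 dilutions without
#' plaques; 3 plaques with EOP in `[eop_lo, eop_mid]` (and anything below
#' order-unity) or lysis at the highest 4-5 dilutions without plaques; 4 EOP
#' of ~1 with increased turbidity or reduced plaque size; 5 EOP of ~1 with no
#' phenotypic difference; 6 EOP of ~1 with reduced turbidity or increased
#' plaque size. "EOP of ~1" is read as order-unity (`eop >= eop_unity`).
#'
#' @param obs A `plate_observation`.
#' @param eop_lo,eop_mid,eop_unity Configurable EOP bin edges (defaults 1e-3,
#'   1e-1, 0.5).
#' @return Integer infection score in 0..6.
#' @export
score_observation <- function(obs, eop_lo = 1e-3, eop_mid = 1e-1, eop_unity = 0.5) {
  stopifnot(inherits(obs, "plate_observation"))
  if (!obs$plaques_present) {
    st <- obs$spot_titers_with_lysis
    if (st == 0L) return(0L)
    if (st <= 2L) return(1L)
    if (st == 3L) return(2L)
    return(3L)  # lysis at highest 4-5 (or more) dilutions, no plaques
  }
  eop <- obs$eop
  if (eop < eop_lo) return(2L)
  if (eop < eop_unity) return(3L)
  # order-unity EOP: phenotype relative to control decides 4/5/6
  if (obs$turbidity == "increased" || obs$plaque_size == "reduced") return(4L)
  if (obs$turbidity == "reduced" || obs$plaque_size == "increased") return(6L)
  5L
}

#' The packaged infection-scoring rubric
#'
#' Returns the shipped transcription of the 0-6 ordinal scoring rubric that
#' [score_observation()] encodes.
#'
#' @return `data.frame` with `score` and `description`.
#' @export
scoring_rubric <- function() {
  read.delim(system.file("extdata", "infection_rubric.tsv", package = "mesoimmunity"),
             stringsAsFactors = FALSE)
}

#' Aggregate replicate assays into an immunity matrix
#'
#' Averages replicate infection scores per (challenger, defender,
#' defender_kind) and returns the challenger x defender grid of mean, n, min
#' and max, as used for the heat-map matrix of averaged scores.
#'
#' @param records Assay records (see [read_assay_table()] / [assay_record()]).
#' @return Object of class `immunity_matrix`: list with matrices `mean`, `n`,
#'   `min`, `max` (challengers in rows, defenders in columns) and the
#'   `defender_kind` vector (one kind per defender column).
#' @export
aggregate_replicates <- function(records) {
  if (nrow(records) == 0L) {
    m <- matrix(numeric(0), 0, 0)
    return(structure(list(mean = m, n = m, min = m, max = m,
                          defender_kind = character(0)), class = "immunity_matrix"))
  }
  kinds <- tapply(records$defender_kind, records$defender,
                  function(k) unique(as.character(k)))
  bad <- names(kinds)[lengths(kinds) > 1]
  if (length(bad))
    stop("conflicting defender_kind for defender(s): ", paste(bad, collapse = ","))
  challengers <- sort(unique(records$challenger))
  defenders <- sort(unique(records$defender))
  mk <- function(fill) matrix(fill, length(challengers), length(defenders),
                              dimnames = list(challengers, defenders))
  M <- list(mean = mk(NA_real_), n = mk(0L), min = mk(NA_real_), max = mk(NA_real_))
  key <- paste(records$challenger, records$defender, sep = "\r")
  for (kk in unique(key)) {
    rows <- records[key == kk, , drop = FALSE]
    scores <- unlist(lapply(rows$scores, function(s) if (length(s) == 1L && is.na(s[1])) NULL else s))
    if (is.null(scores)) {
      # summary-only rows: pool via stored summaries
      ntot <- sum(rows$n)
      mean_s <- sum(rows$mean_score * rows$n) / ntot
      mn <- min(rows$min_score); mx <- max(rows$max_score)
    } else {
      ntot <- length(scores); mean_s <- mean(scores); mn <- min(scores); mx <- max(scores)
    }
    ch <- rows$challenger[1]; de <- rows$defender[1]
    M$mean[ch, de] <- mean_s; M$n[ch, de] <- ntot
    M$min[ch, de] <- mn; M$max[ch, de] <- mx
  }
  structure(list(mean = M$mean, n = M$n, min = M$min, max = M$max,
                 defender_kind = vapply(kinds[defenders], identity, character(1))),
            class = "immunity_matrix")
}

#' @export
print.immunity_matrix <- function(x, ...) {
  cat("<immunity_matrix> ", nrow(x$mean), " challengers x ", ncol(x$mean),
      " defenders (", sum(x$n > 0), " scored cells)\n", sep = "")
  invisible(x)
}

#' @export
summary.immunity_matrix <- function(object, ...) {
  sc <- object$mean[object$n > 0]
  cat("scored cells:", length(sc), "\n")
  if (length(sc)) {
    cat("score distribution (rounded):\n")
    print(table(round(sc)))
  }
  invisible(object)
}

# defender column name -> phage id (lysogen columns are named by their prophage)
lysogen_columns <- function(matrix) {
  which(matrix$defender_kind == "lysogen")
}

#' Reciprocal asymmetry of averaged infection scores
#'
#' For every unordered phage pair with both reciprocal lysogen assays present
#' (A challenging the B lysogen and B challenging the A lysogen), computes
#' the absolute difference of averaged infection scores, `delta = |I_AB - I_BA|`.
#' Pairs with only one direction tested are excluded.
#'
#' @param matrix An `immunity_matrix` (lysogen defender columns are named by
#'   their prophage's phage id).
#' @return `data.frame` with `phage_a`, `phage_b`, `i_ab`, `i_ba`, `delta`.
#' @export
reciprocal_asymmetry <- function(matrix) {
  lys <- colnames(matrix$mean)[lysogen_columns(matrix)]
  both <- intersect(lys, rownames(matrix$mean))
  out <- data.frame(phage_a = character(), phage_b = character(),
                    i_ab = numeric(), i_ba = numeric(), delta = numeric(),
                    stringsAsFactors = FALSE)
  if (length(both) < 2) return(out)
  skipped <- 0L
  for (i in seq_along(both)) {
    for (j in seq_along(both)) {
      if (j <= i) next
      A <- both[i]; B <- both[j]
      iab <- if (matrix$n[A, B] > 0) matrix$mean[A, B] else NA
      iba <- if (matrix$n[B, A] > 0) matrix$mean[B, A] else NA
      if (is.na(iab) || is.na(iba)) { skipped <- skipped + 1L; next }
      out <- rbind(out, data.frame(phage_a = A, phage_b = B, i_ab = iab, i_ba = iba,
                                   delta = abs(iab - iba), stringsAsFactors = FALSE))
    }
  }
  attr(out, "one_directional_excluded") <- skipped
  out
}

#' Correlation between two phages' superinfection profiles
#'
#' Along the challenging axis, correlates the two phages' rows (their scores
#' against the shared panel of lysogen defenders); along the defending axis,
#' correlates the two phages' lysogen columns (the panel's scores against the
#' two lysogens). Pearson by default.
#'
#' @param matrix An `immunity_matrix`.
#' @param A,B Phage ids.
#' @param axis `"challenging"` or `"defending"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `axis`, `r` (or `NA` when degenerate), `n_shared`.
#' @export
profile_correlation <- function(matrix, A, B, axis = c("challenging", "defending"),
                                method = c("pearson", "spearman")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  lys <- lysogen_columns(matrix)
  if (axis == "challenging") {
    x <- matrix$mean[A, lys]; y <- matrix$mean[B, lys]
    nx <- matrix$n[A, lys]; ny <- matrix$n[B, lys]
  } else {
    x <- matrix$mean[, A]; y <- matrix$mean[, B]
    nx <- matrix$n[, A]; ny <- matrix$n[, B]
  }
  ok <- nx > 0 & ny > 0 & !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 shared scored entries")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(axis = axis, r = NA_real_, n_shared = sum(ok), degenerate = TRUE))
  list(axis = axis, r = cor(x, y, method = method), n_shared = sum(ok),
       degenerate = FALSE)
}

#' Regress immunity phenotype on a genotype distance
#'
#' Ordinary least squares of the averaged infection score (or the reciprocal
#' asymmetry) on a pairwise genotype distance, optionally restricted to a
#' clade (e.g., only intra-clade comparisons, the default scope used for all
#' reported R-squared values).
#'
#' @param matrix An `immunity_matrix`.
#' @param distances A `distance_table`.
#' @param response `"I"` (per-directed-assay averaged score) or `"dI"`
#'   (reciprocal-pair absolute difference).
#' @param metric Distance metric name in `distances`.
#' @param clade Optional character vector of phage ids; only pairs with both
#'   members in it are used.
#' @return Object of class `phenotype_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, the underlying points and the `lm` fit.
#' @export
regress_phenotype_vs_distance <- function(matrix, distances, response = c("I", "dI"),
                                          metric = "D_Stop_motif", clade = NULL) {
  response <- match.arg(response)
  D <- distances$matrices[[metric]]
  if (is.null(D)) stop("unknown metric '", metric, "'")
  pts <- regression_points(matrix, D, response, clade)
  pts <- pts[!is.na(pts$x) & !is.na(pts$y), , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 points after scope filtering")
  fit <- lm(y ~ x, data = pts)
  structure(list(metric = metric, response = response,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, n = nrow(pts),
                 points = pts, fit = fit),
            class = "phenotype_regression")
}

regression_points <- function(matrix, D, response, clade) {
  if (response == "I") {
    lys <- colnames(matrix$mean)[lysogen_columns(matrix)]
    out <- data.frame(x = numeric(), y = numeric())
    for (ch in rownames(matrix$mean)) for (de in lys) {
      if (matrix$n[ch, de] == 0) next
      if (!is.null(clade) && !(ch %in% clade && de %in% clade)) next
      if (!(ch %in% rownames(D)) || !(de %in% rownames(D)) || is.na(D[ch, de])) next
      out <- rbind(out, data.frame(x = D[ch, de], y = matrix$mean[ch, de]))
    }
    out
  } else {
    ra <- reciprocal_asymmetry(matrix)
    if (!is.null(clade))
      ra <- ra[ra$phage_a %in% clade & ra$phage_b %in% clade, , drop = FALSE]
    ok <- ra$phage_a %in% rownames(D) & ra$phage_b %in% rownames(D)
    ra <- ra[ok, , drop = FALSE]
    data.frame(x = D[cbind(ra$phage_a, ra$phage_b)], y = ra$delta)
  }
}

#' @export
print.phenotype_regression <- function(x, ...) {
  cat("<phenotype_regression> ", x$response, " ~ ", x$metric, "\n", sep = "")
  cat(sprintf("  slope %.4f, intercept %.4f, R^2 %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.phenotype_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Lysogen-versus-CRS score differences
#'
#' Pairs each lysogen defender with the cognate cloned-repressor strain (CRS)
#' of the same immunity system and, for every challenger scored on both,
#' reports `I_CRS - I_Lysogen`. CRS columns are matched to lysogens by the
#' `crs_map` (CRS column name -> lysogen phage id); by default a CRS column
#' named `"<phage>_CRS"` pairs with the `"<phage>"` lysogen.
#'
#' @param matrix An `immunity_matrix`.
#' @param crs_map Optional named character vector mapping CRS column names to
#'   lysogen column names.
#' @return `data.frame` with `challenger`, `system`, `i_lysogen`, `i_crs`,
#'   `delta` (`I_CRS - I_Lysogen`). Unpaired systems are skipped with a
#'   warning.
#' @export
lysogen_crs_delta <- function(matrix, crs_map = NULL) {
  cols <- colnames(matrix$mean)
  crs_cols <- cols[matrix$defender_kind == "CRS"]
  lys_cols <- cols[matrix$defender_kind == "lysogen"]
  if (is.null(crs_map)) {
    crs_map <- setNames(sub("_CRS$", "", crs_cols), crs_cols)
  }
  out <- data.frame(challenger = character(), system = character(),
                    i_lysogen = numeric(), i_crs = numeric(), delta = numeric(),
                    stringsAsFactors = FALSE)
  for (cc in crs_cols) {
    lys <- crs_map[[cc]]
    if (is.null(lys) || is.na(lys) || !(lys %in% lys_cols)) {
      warning("CRS column '", cc, "' has no cognate lysogen; skipped")
      next
    }
    for (ch in rownames(matrix$mean)) {
      if (matrix$n[ch, cc] == 0 || matrix$n[ch, lys] == 0) next
      out <- rbind(out, data.frame(
        challenger = ch, system = lys,
        i_lysogen = matrix$mean[ch, lys], i_crs = matrix$mean[ch, cc],
        delta = matrix$mean[ch, cc] - matrix$mean[ch, lys],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Summary counts over a collection of assay records
#'
#' Reports the totals used to describe an assay campaign: total individual
#' assays (sum of replicates), unique (challenger, defender, kind)
#' comparisons, unordered reciprocal lysogen pairs with both directions
#' tested, lysogen-CRS paired comparisons (two per complete pair sharing a
#' challenger), the percentage of unique comparisons measured with two or
#' more replicates, and the percentage of those whose replicate score range
#' is below 2.
#'
#' @param records Assay records.
#' @param crs_map Optional CRS-to-lysogen map as in [lysogen_crs_delta()].
#' @return Named list of counts/percentages.
#' @export
summarize_assay_counts <- function(records, crs_map = NULL) {
  if (nrow(records) == 0L)
    return(list(total_assays = 0L, unique_comparisons = 0L, reciprocal_pairs = 0L,
                lysogen_crs_paired_comparisons = 0L, pct_multireplicate = 0,
                pct_multireplicate_range_lt2 = 0))
  key <- paste(records$challenger, records$defender, records$defender_kind, sep = "\r")
  total_assays <- sum(records$n)
  uniq <- !duplicated(key)
  unique_comparisons <- sum(uniq)
  # per-comparison pooled n and range
  n_by <- tapply(records$n, key, sum)
  rng_by <- tapply(seq_len(nrow(records)), key, function(ix) {
    max(records$max_score[ix]) - min(records$min_score[ix])
  })
  multi <- n_by >= 2
  pct_multi <- 100 * mean(multi)
  pct_rng <- if (any(multi)) 100 * mean(rng_by[multi] < 2) else 0
  m <- aggregate_replicates(records)
  reciprocal_pairs <- nrow(reciprocal_asymmetry(m))
  crs_tab <- suppressWarnings(lysogen_crs_delta(m, crs_map = crs_map))
  list(total_assays = as.integer(total_assays),
       unique_comparisons = as.integer(unique_comparisons),
       reciprocal_pairs = as.integer(reciprocal_pairs),
       lysogen_crs_paired_comparisons = as.integer(2L * nrow(crs_tab)),
       pct_multireplicate = pct_multi,
       pct_multireplicate_range_lt2 = pct_rng)
}
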