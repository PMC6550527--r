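#' Design a 30-bp EMSA substrate around a stoperator site
#'
#' A binding substrate is a 30-bp duplex consisting of the 13-bp stoperator
#' site flanked by 8 bp upstream and 9 bp downstream of genomic sequence
#' (top-strand coordinates), so the core occupies positions 9-21 of the
#' substrate.
#'
#' @param genome A `phage_genome` or DNA string.
#' @param site One site row (`start`, `end`; a width-13 site).
#' @return Object of class `substrate_spec`: list with `sequence` (30 bp),
#'   `core` (13 bp), `core_start` (9), `genome_start`, `genome_end`.
#' @export
design_substrate <- function(genome, site) {
  seq <- if (inherits(genome, "phage_genome")) genome$sequence else toupper(as.character(genome))
  w <- site$end - site$start + 1
  if (w != 13) stop("substrate design expects a 13-bp core site")
  lo <- site$start - 8L
  hi <- site$end + 9L
  if (lo < 1L || hi > nchar(seq))
    stop("site too close to a genome terminus for 8+9 bp flanks")
  structure(list(sequence = substr(seq, lo, hi),
                 core = substr(seq, site$start, site$end),
                 core_start = 9L, genome_start = lo, genome_end = hi),
            class = "substrate_spec")
}

#' Progressive substitution series between two stoperator sites
#'
#' Given a source and a target 13-mer, enumerates substrates in which subsets
#' of the differing positions are converted from source to target base. With
#' an `anchor_position`, only subsets containing the anchor are produced
#' (2^(k-1) substrates for k differing positions), ordered by subset size
#' then position; without an anchor, all non-empty subsets (2^k - 1). The
#' final substrate carries the target base at every differing position. Each
#' substrate is labelled like `"C9G10C11A12"` (target base + core position).
#'
#' @param site_from,site_to Equal-width site strings.
#' @param anchor_position Optional differing position always included.
#' @param flank5,flank3 Flanking sequences kept invariable (source-substrate
#'   flanks); defaults are empty strings, giving bare 13-mers.
#' @return `data.frame` with `label`, `positions` (semicolon-joined),
#'   `core`, `sequence`; zero rows for identical sites.
#' @export
substitution_series <- function(site_from, site_to, anchor_position = NULL,
                                flank5 = "", flank3 = "") {
  site_from <- toupper(site_from); site_to <- toupper(site_to)
  if (nchar(site_from) != nchar(site_to)) stop("sites must have equal width")
  f <- strsplit(site_from, "")[[1]]
  t <- strsplit(site_to, "")[[1]]
  diffs <- which(f != t)
  empty <- data.frame(label = character(), positions = character(),
                      core = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (!length(diffs)) return(empty)
  if (!is.null(anchor_position)) {
    if (!(anchor_position %in% diffs)) stop("anchor must be a differing position")
    rest <- setdiff(diffs, anchor_position)
    subsets <- lapply(0:(2^length(rest) - 1), function(mask) {
      sort(c(anchor_position, rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0]))
    })
  } else {
    subsets <- lapply(1:(2^length(diffs) - 1), function(mask) {
      diffs[bitwAnd(mask, 2^(seq_along(diffs) - 1)) > 0]
    })
  }
  # order by subset size, then lexicographically by positions
  keys <- vapply(subsets, function(p) sprintf("%02d-%s", length(p),
                 paste(sprintf("%02d", p), collapse = ",")), character(1))
  subsets <- subsets[order(keys)]
  rows <- lapply(subsets, function(p) {
    core <- f
    core[p] <- t[p]
    data.frame(label = paste0(t[p], p, collapse = ""),
               positions = paste(p, collapse = ";"),
               core = paste(core, collapse = ""),
               sequence = paste0(flank5, paste(core, collapse = ""), flank3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a binding titration series
#'
#' @param concentrations Repressor concentrations (nM), strictly increasing.
#' @param fraction_bound Fraction of DNA bound at each concentration; values
#'   given as percentages (max > 1.5) are normalized to fractions.
#' @param substrate Substrate identifier.
#' @return Object of class `binding_series`.
#' @export
binding_series <- function(concentrations, fraction_bound, substrate = NA_character_) {
  if (length(concentrations) != length(fraction_bound))
    stop("concentrations and fraction_bound differ in length")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop("concentrations must be non-negative and strictly increasing")
  if (max(fraction_bound, na.rm = TRUE) > 1.5) fraction_bound <- fraction_bound / 100
  structure(list(substrate = substrate, concentrations = as.numeric(concentrations),
                 fraction_bound = as.numeric(fraction_bound)),
            class = "binding_series")
}

#' Read a titration series from CSV
#'
#' Expects columns `concentration_nM` and `fraction_bound` (or
#' `percent_bound`).
#'
#' @param path CSV path.
#' @param substrate Substrate identifier.
#' @return A `binding_series`.
#' @export
read_binding_series <- function(path, substrate = NA_character_) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  y <- if ("fraction_bound" %in% names(tb)) tb$fraction_bound else tb$percent_bound
  binding_series(tb$concentration_nM, y, substrate = substrate)
}

#' Fit a one-site specific binding curve
#'
#' Least-squares fit of `Y = Bmax * X / (KD + X)` to a titration series
#' (bounded: KD > 0, 0 < Bmax <= `bmax_upper`), with deterministic
#' multi-start from the minimum, median and maximum concentration. The
#' standard error of KD comes from the fit covariance.
#'
#' @param series A `binding_series` (or anything coercible: list with
#'   `concentrations`, `fraction_bound`).
#' @param bmax_upper Upper bound on Bmax (mild, default 1.2).
#' @return Object of class `binding_fit`: `kd` (nM), `bmax`, `kd_stderr`,
#'   `bmax_stderr`, `converged`, `message`, plus the data. For
#'   monotone-zero data `kd` is an above-range sentinel (1000 x max
#'   concentration) with `converged = FALSE`.
#' @export
fit_one_site <- function(series, bmax_upper = 1.2) {
  x <- series$concentrations
  y <- series$fraction_bound
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite points")
  if (all(y < 0.02)) {
    return(structure(list(kd = 1000 * max(x), bmax = NA_real_, kd_stderr = NA_real_,
                          bmax_stderr = NA_real_, converged = FALSE,
                          message = "no binding detected (above-range KD sentinel)",
                          concentrations = x, fraction_bound = y),
                     class = "binding_fit"))
  }
  df <- data.frame(x = x, y = y)
  starts <- unique(pmax(c(min(x[x > 0], na.rm = TRUE), median(x), max(x)), 1e-9))
  best <- NULL
  for (kd0 in starts) {
    fit <- tryCatch(
      nls(y ~ bmax * x / (kd + x), data = df,
          start = list(kd = kd0, bmax = min(max(y), bmax_upper)),
          lower = c(kd = 1e-12, bmax = 1e-6), upper = c(kd = Inf, bmax = bmax_upper),
          algorithm = "port", control = list(warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, kd_stderr = NA_real_,
                          bmax_stderr = NA_real_, converged = FALSE,
                          message = "fit did not converge",
                          concentrations = x, fraction_bound = y),
                     class = "binding_fit"))
  }
  co <- summary(best$fit)$coefficients
  structure(list(kd = unname(co["kd", "Estimate"]), bmax = unname(co["bmax", "Estimate"]),
                 kd_stderr = unname(co["kd", "Std. Error"]),
                 bmax_stderr = unname(co["bmax", "Std. Error"]),
                 converged = TRUE, message = "OK",
                 concentrations = x, fraction_bound = y, fit = best$fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<binding_fit> KD = %.3g nM (SE %.2g), Bmax = %.3f\n",
                x$kd, x$kd_stderr, x$bmax))
  else cat("<binding_fit> not converged:", x$message, "\n")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, bmax = object$bmax)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$concentrations else
    if (is.list(newdata)) newdata$x %||% newdata$concentrations else newdata
  object$bmax * x / (object$kd + x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
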