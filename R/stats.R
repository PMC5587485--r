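## Correspondence statistics: nightly proportions, Pearson correlation,
## contingency tables, exact r x c tests with Bonferroni control, and
## sampled-airspace geometry.

#' Average nightly synchronous proportion
#'
#' Unweighted mean of the defined nightly proportions (nights with no
#' visual detections are excluded).
#'
#' @param tally data.frame from \code{\link{nightlyTally}} (per-night rows)
#' @return percentage
#' @export
averageNightlyProportion <- function(tally) {
  p <- tally$proportion_pct[!is.na(tally$proportion_pct) &
                              !tally$night %in% c("Total", "Average")]
  if (!length(p)) stop("no nights with visual detections")
  mean(p)
}

#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation r and the two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant)
#' @return list(r, t, df, p)
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, df = n - 2, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' Exact test for an r x c contingency table
#'
#' Fully enumerates the tables with the observed margins; each table's
#' probability under the multivariate hypergeometric null is computed via
#' log-factorials, and the two-sided p-value sums the probabilities not
#' exceeding the observed table's probability (relative tie tolerance
#' 1e-7, applied on the log scale so that strongly unbalanced tables with
#' very small observed probabilities are handled exactly).  Degenerate
#' margins (a zero row or column) give p = 1.
#'
#' @param tab integer matrix of counts (>= 2 x 2, total <= 10000)
#' @return list(p, n_tables, prob_sum) where prob_sum is the enumeration
#'   completeness check (should be 1)
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  N <- sum(tab)
  if (N > 10000) stop("enumeration bound exceeded (total > 10000)")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0) || N == 0)
    return(list(p = 1, n_tables = 1L, prob_sum = 1))
  logconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- logconst - sum(lgamma(tab + 1))
  env <- new.env()
  env$prob_sum <- 0; env$p_sum <- 0; env$count <- 0L
  enumTables(rs, cs, logconst, logp_obs, env)
  list(p = min(1, env$p_sum), n_tables = env$count,
       prob_sum = env$prob_sum)
}

# Depth-first enumeration over rows: for each composition of a row
# compatible with the remaining column margins, recurse; the last row is
# forced.  Accumulates the total probability mass (completeness check)
# and the two-sided p mass (tables no more probable than observed).
enumTables <- function(rs, cs, logconst, logp_obs, env) {
  nr <- length(rs)
  recurse <- function(rowi, cs_left, logacc) {
    if (rowi == nr) {
      logpr <- logconst + logacc - sum(lgamma(cs_left + 1))
      pr <- exp(logpr)
      env$prob_sum <- env$prob_sum + pr
      env$count <- env$count + 1L
      if (logpr <= logp_obs + 1e-7) env$p_sum <- env$p_sum + pr
      return(invisible())
    }
    for (comp in rowCompositions(rs[rowi], cs_left)) {
      recurse(rowi + 1, cs_left - comp, logacc - sum(lgamma(comp + 1)))
    }
  }
  recurse(1, cs, 0)
}

# All ways to split total n over cells with caps (the remaining column
# sums).  Returns a list of integer vectors.
rowCompositions <- function(n, caps) {
  k <- length(caps)
  out <- list()
  comp <- integer(k)
  gen <- function(j, left) {
    if (j == k) {
      if (left <= caps[k]) {
        comp[k] <<- left
        out[[length(out) + 1]] <<- comp
      }
      return(invisible())
    }
    hi <- min(caps[j], left)
    lo <- max(0, left - sum(caps[(j + 1):k]))
    if (hi < lo) return(invisible())
    for (v in lo:hi) {
      comp[j] <<- v
      gen(j + 1, left - v)
    }
  }
  gen(1, n)
  out
}

#' Bonferroni family-wise error control
#'
#' @param p_values raw p-values in (0, 1]
#' @param n_tests family size (default: length of the input)
#' @return data.frame: p_raw, p_adjusted (min(1, n_tests * p)), method,
#'   n_tests
#' @export
bonferroni <- function(p_values, n_tests = length(p_values)) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  adj <- pmin(1, stats::p.adjust(p_values, method = "bonferroni",
                                 n = n_tests))
  data.frame(p_raw = p_values, p_adjusted = adj, method = "bonferroni",
             n_tests = n_tests)
}

#' Sampled-airspace volumes of camera and microphone
#'
#' The camera frustum is approximated by a rectangular pyramid of depth d
#' whose base is the field of view at d (width and height from the
#' pinhole model, rounded to whole metres, the reporting convention for
#' the published field-of-view footprint); the omnidirectional microphone
#' samples the hemisphere of radius d above ground.
#'
#' @param camera a \code{\link{CameraModel}}
#' @param range_m evaluation distance d, metres
#' @return list(v_camera_m3, v_mic_m3, ratio_pct, fov_w_m, fov_h_m)
#' @export
samplingVolumes <- function(camera, range_m = 50) {
  stopifnot(range_m > 0)
  f <- focalPx(camera)
  w <- round(range_m * camera@width_px / f)
  h <- round(range_m * camera@height_px / f)
  v_cam <- w * h * range_m / 3
  v_mic <- 2 / 3 * pi * range_m^3
  list(v_camera_m3 = v_cam, v_mic_m3 = v_mic,
       ratio_pct = 100 * v_cam / v_mic, fov_w_m = w, fov_h_m = h)
}

#' Contingency tables of acoustic correspondence
#'
#' Builds the printed-table shapes from labelled video events: proximity
#' x acoustics, flight type x acoustics within each proximity class, and
#' (for multi-bat events) interaction x acoustics within proximity.
#'
#' @param events data.frame with proximity, flight, n_bats, interaction
#'   and a logical synchronous column
#' @return list of integer matrices: proximity, flight (named list by
#'   proximity class), interaction (multi-bat subset, by proximity)
#' @export
buildContingencyTables <- function(events) {
  lv_prox <- c("near", "mid", "far")
  lv_fl <- c("straight", "curved", "erratic")
  acou <- factor(ifelse(events$synchronous, "acoustics", "no_acoustics"),
                 levels = c("acoustics", "no_acoustics"))
  prox <- factor(events$proximity, levels = lv_prox)
  tab_prox <- table(proximity = prox, acoustics = acou)
  tab_fl <- lapply(setNames(lv_prox, lv_prox), function(pc) {
    sub <- events[events$proximity == pc, , drop = FALSE]
    table(flight = factor(sub$flight, levels = lv_fl),
          acoustics = factor(ifelse(sub$synchronous, "acoustics",
                                    "no_acoustics"),
                             levels = c("acoustics", "no_acoustics")))
  })
  multi <- events[events$n_bats >= 2, , drop = FALSE]
  tab_int <- lapply(setNames(lv_prox, lv_prox), function(pc) {
    sub <- multi[multi$proximity == pc, , drop = FALSE]
    table(interaction = factor(ifelse(sub$interaction == "agonistic",
                                      "yes", "no"), levels = c("yes", "no")),
          acoustics = factor(ifelse(sub$synchronous, "acoustics",
                                    "no_acoustics"),
                             levels = c("acoustics", "no_acoustics")))
  })
  list(proximity = unclass(tab_prox),
       flight = lapply(tab_fl, unclass),
       interaction = lapply(tab_int, unclass))
}

#' Formatted correspondence table with subtotals and percentages
#'
#' Reproduces the printed layout: per proximity class one row per flight
#' type with counts and within-row percentages, a subtotal row per class,
#' and an overall total.  Percentages are rounded half-up to integers.
#'
#' @param events labelled events as in \code{\link{buildContingencyTables}}
#' @param by group rows by "flight" or "interaction"
#' @return data.frame with columns proximity, group, acoustics_n,
#'   acoustics_pct, no_acoustics_n, no_acoustics_pct, subtotal_n,
#'   subtotal_pct
#' @export
correspondenceTable <- function(events, by = c("flight", "interaction")) {
  by <- match.arg(by)
  if (by == "interaction") {
    events <- events[events$n_bats >= 2, , drop = FALSE]
    events$group <- ifelse(events$interaction == "agonistic", "yes", "no")
    lv_g <- c("yes", "no")
  } else {
    events$group <- events$flight
    lv_g <- c("straight", "curved", "erratic")
  }
  lv_prox <- c("near", "mid", "far")
  n_all <- nrow(events)
  rows <- list()
  for (pc in lv_prox) {
    sub <- events[events$proximity == pc, , drop = FALSE]
    n_sub <- nrow(sub)
    for (gv in lv_g) {
      s2 <- sub[sub$group == gv, , drop = FALSE]
      a <- sum(s2$synchronous); na <- sum(!s2$synchronous); tot <- nrow(s2)
      rows[[length(rows) + 1]] <- data.frame(
        proximity = pc, group = gv, acoustics_n = a,
        acoustics_pct = pctOf(a, tot), no_acoustics_n = na,
        no_acoustics_pct = pctOf(na, tot), subtotal_n = tot,
        subtotal_pct = pctOf(tot, n_sub))
    }
    a <- sum(sub$synchronous); na <- sum(!sub$synchronous)
    rows[[length(rows) + 1]] <- data.frame(
      proximity = pc, group = "Subtotal", acoustics_n = a,
      acoustics_pct = pctOf(a, n_sub), no_acoustics_n = na,
      no_acoustics_pct = pctOf(na, n_sub), subtotal_n = n_sub,
      subtotal_pct = pctOf(n_sub, n_all))
  }
  a <- sum(events$synchronous); na <- sum(!events$synchronous)
  rows[[length(rows) + 1]] <- data.frame(
    proximity = "", group = "Total", acoustics_n = a,
    acoustics_pct = pctOf(a, n_all), no_acoustics_n = na,
    no_acoustics_pct = pctOf(na, n_all), subtotal_n = n_all,
    subtotal_pct = 100)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pctOf <- function(x, total) {
  if (total == 0) return(0)
  roundHalfUp(100 * x / total)
}

#' Share of multi-bat events among visual detections
#'
#' @param events data.frame with an n_bats column
#' @return percentage, rounded half-up to an integer
#' @export
multiBatShare <- function(events) {
  pctOf(sum(events$n_bats >= 2), nrow(events))
}
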