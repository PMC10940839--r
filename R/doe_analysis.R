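#' Build a factorial liquid-handling design
#'
#' Full crossing of aspiration and dispension speeds (and optionally needle
#' depth), each combination assigned to `replicates` culture wells, observed
#' at every time level. Factor levels are treated as categorical. The
#' default second-design levels are 4 aspiration speeds up to 500 uL/s
#' (about 5x manual speed) crossed with 2 dispension speeds.
#'
#' @param aspiration Aspiration-speed levels in uL/s.
#' @param dispension Dispension-speed levels in uL/s.
#' @param needle_depth Optional needle-depth levels in mm.
#' @param time Optional observation days; every run is observed at each.
#' @param replicates Wells per factor combination (>= 1).
#' @param platform Platform label attached to the design.
#' @return Data frame of class `doe_design` with columns `run_id`,
#'   `plate_well`, `aspiration`, `dispension` (and `needle_depth`, `day`
#'   when given), `replicate`, one row per run x time observation.
#' @examples
#' build_design(aspiration = c(37, 100), dispension = c(37, 100),
#'              needle_depth = c(1, 2))  # 2^3: 8 runs
#' @export
build_design <- function(aspiration = c(100, 200, 350, 500),
                         dispension = c(100, 200),
                         needle_depth = NULL, time = NULL,
                         replicates = 1, platform = "A400") {
  factors <- list(aspiration = aspiration, dispension = dispension)
  if (!is.null(needle_depth)) factors$needle_depth <- needle_depth
  if (any(lengths(factors) == 0)) {
    stop("every factor needs at least one level", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  n_levels <- c(lengths(factors), time = length(unique(time)))
  if (sum(n_levels >= 2) < 1) {
    stop("at least one factor must have two or more levels", call. = FALSE)
  }
  runs <- expand.grid(c(factors, list(replicate = seq_len(replicates))),
                      KEEP.OUT.ATTRS = FALSE)
  runs$run_id <- seq_len(nrow(runs))
  runs$plate_well <- sprintf("W%02d", runs$run_id)
  if (!is.null(time)) {
    runs <- merge(runs, data.frame(day = sort(unique(time))), by = NULL)
    runs <- runs[order(runs$run_id, runs$day), , drop = FALSE]
  }
  rownames(runs) <- NULL
  front <- intersect(c("run_id", "plate_well", "aspiration", "dispension",
                       "needle_depth", "day", "replicate"), names(runs))
  runs <- runs[, front, drop = FALSE]
  attr(runs, "platform") <- platform
  class(runs) <- c("doe_design", "data.frame")
  runs
}

#' Analysis of variance for empty-microwell percentages
#'
#' Fits the factorial model `pct_empty ~ aspiration * dispension + time`
#' with all factors categorical, using sequential sums of squares (equal to
#' marginal sums on balanced designs; a warning is issued for unbalanced
#' inputs) and F tests against the residual mean square. Significance is
#' flagged at alpha = 0.05 with the conventional star codes
#' (* < .05, ** < .01, *** < .001, **** < .0001).
#'
#' @param design A [build_design()] data frame.
#' @param response Numeric vector of per-run empty-well percentages,
#'   parallel to the design rows.
#' @return Data frame of class `anova_table` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `statistic`, `p_value`, `signif`.
#' @export
fit_anova <- function(design, response) {
  if (length(response) != nrow(design)) {
    stop("response length must equal the number of design rows",
         call. = FALSE)
  }
  if (!all(is.finite(response))) {
    stop("response must be finite", call. = FALSE)
  }
  if (var(response) == 0) {
    stop("degenerate response: constant values carry no information",
         call. = FALSE)
  }
  df <- data.frame(pct_empty = response,
                   aspiration = factor(design$aspiration),
                   dispension = factor(design$dispension))
  rhs <- c("aspiration", "dispension")
  if (!is.null(design$day) && length(unique(design$day)) > 1) {
    df$time <- factor(design$day)
    rhs <- c(rhs, "time")
  }
  if (nlevels(df$aspiration) > 1 && nlevels(df$dispension) > 1) {
    rhs <- c(rhs, "aspiration:dispension")
  }
  rhs <- rhs[vapply(sub(":.*", "", rhs), function(v)
    nlevels(df[[v]]) > 1, logical(1))]
  if (length(rhs) == 0) {
    stop("no factor with two or more levels to analyse", call. = FALSE)
  }
  cell <- interaction(df[setdiff(names(df), "pct_empty")], drop = TRUE)
  if (length(unique(table(cell))) > 1) {
    warning("design is unbalanced: sequential sums of squares depend on ",
            "term order", call. = FALSE)
  }
  form <- stats::as.formula(paste("pct_empty ~", paste(rhs, collapse = " + ")))
  fit <- aov(form, data = df)
  if (stats::df.residual(fit) == 0) {
    stop("zero residual degrees of freedom: the model is saturated",
         call. = FALSE)
  }
  tab <- as.data.frame(summary(fit)[[1]])
  term <- trimws(rownames(tab))
  out <- data.frame(term = term, df = tab$Df, sum_sq = tab$`Sum Sq`,
                    mean_sq = tab$`Mean Sq`, statistic = tab$`F value`,
                    p_value = tab$`Pr(>F)`)
  order_pref <- c("aspiration", "dispension", "aspiration:dispension",
                  "time", "Residuals")
  out <- out[order(match(out$term, order_pref)), , drop = FALSE]
  out$signif <- vapply(out$p_value, function(p) {
    if (is.na(p)) "" else if (p < 1e-4) "****" else if (p < 1e-3) "***"
    else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }, character(1))
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Main-effect and interaction summaries
#'
#' Per factor level: mean and SD of the response (main-effects view); per
#' factor-pair level combination: cell means (interaction view), in tidy
#' long format for plotting.
#'
#' @inheritParams fit_anova
#' @return A list with data frames `main` (`factor`, `level`, `mean`, `sd`,
#'   `n`) and `interaction` (`factor_a`, `level_a`, `factor_b`, `level_b`,
#'   `mean`, `sd`, `n`).
#' @export
effect_summaries <- function(design, response) {
  if (length(response) != nrow(design)) {
    stop("response length must equal the number of design rows",
         call. = FALSE)
  }
  facs <- intersect(c("aspiration", "dispension", "needle_depth", "day"),
                    names(design))
  facs <- facs[vapply(facs, function(f)
    length(unique(design[[f]])) > 1, logical(1))]
  main <- do.call(rbind, lapply(facs, function(f) {
    lv <- split(response, design[[f]])
    data.frame(factor = f, level = names(lv),
               mean = vapply(lv, mean, numeric(1)),
               sd = vapply(lv, function(v) if (length(v) > 1) sd(v) else 0,
                           numeric(1)),
               n = lengths(lv), row.names = NULL)
  }))
  pairs <- if (length(facs) >= 2) utils::combn(facs, 2, simplify = FALSE)
           else list()
  inter <- do.call(rbind, lapply(pairs, function(p) {
    key <- interaction(design[[p[1]]], design[[p[2]]], sep = "\r", drop = TRUE)
    lv <- split(response, key)
    parts <- strsplit(names(lv), "\r", fixed = TRUE)
    data.frame(factor_a = p[1], level_a = vapply(parts, `[`, "", 1),
               factor_b = p[2], level_b = vapply(parts, `[`, "", 2),
               mean = vapply(lv, mean, numeric(1)),
               sd = vapply(lv, function(v) if (length(v) > 1) sd(v) else 0,
                           numeric(1)),
               n = lengths(lv), row.names = NULL)
  }))
  list(main = main, interaction = inter)
}

#' Simulate empty-well responses for a design
#'
#' Runs the [displacement_model()] occupancy simulation for every physical
#' well of a design and returns the empty-well percentage for each design
#' row (well x day observation), providing a ground-truth-driven response
#' for validating the DOE analysis.
#'
#' @param design A [build_design()] data frame with a `day` column.
#' @param layout A `plate_layout`.
#' @param model A [displacement_model()].
#' @param seed Integer seed.
#' @param initial_empty_fraction Day-0 emptiness probability.
#' @return Numeric vector of `pct_empty`, parallel to the design rows.
#' @export
simulate_doe <- function(design, layout, model = displacement_model(),
                         seed = 1, initial_empty_fraction = 0.05) {
  if (is.null(design$day)) {
    stop("design needs a day column (build it with time levels)",
         call. = FALSE)
  }
  response <- rep(NA_real_, nrow(design))
  for (rid in unique(design$run_id)) {
    rows <- which(design$run_id == rid)
    days <- design$day[rows]
    series <- simulate_series(
      layout, model,
      aspiration = design$aspiration[rows[1]],
      dispension = design$dispension[rows[1]],
      timepoints = sort(unique(days)),
      seed = seed + rid,
      initial_empty_fraction = initial_empty_fraction)
    pct <- vapply(series, function(s)
      100 * mean(s$truth$occupancy$status == "empty"), numeric(1))
    names(pct) <- vapply(series, function(s) as.character(s$day),
                         character(1))
    response[rows] <- pct[as.character(days)]
  }
  response
}
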