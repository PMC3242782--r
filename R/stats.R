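#' Group summary (n, mean, SD, median)
#'
#' The column conventions of karyometric result tables: `X` the
#' arithmetic mean, `S` the sample standard deviation (n-1 denominator;
#' 0 for a single value), `Md` the median (midpoint of the two central
#' order statistics for even n).
#'
#' @param values numeric vector, length >= 1, no missing values (exclude
#'   undefined AAR etc. before calling).
#' @return An object of class `group_summary`: list with `n`, `X`, `S`,
#'   `Md`.
#' @examples
#' summarize_group(c(1, 2, 3))   # X=2, S=1, Md=2
#' summarize_group(c(1, 2, 3, 4))$Md  # 2.5
#' @export
summarize_group <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (any(is.na(values)))
    stop("missing values must be excluded before summarizing")
  structure(
    list(n = length(values), X = mean(values),
         S = if (length(values) == 1L) 0 else sd(values),
         Md = median(values)),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n=%d  X=%.4g  S=%.4g  Md=%.4g\n", x$n, x$X, x$S, x$Md))
  invisible(x)
}

#' Two-sample comparison (Student t or Mann-Whitney)
#'
#' Unless a test is forced, each sample is screened with a Shapiro-Wilk
#' normality test at alpha = 0.05: when both samples look normal the
#' two-sided Student t-test (pooled variance) is used, otherwise the
#' two-sided Mann-Whitney test. The Mann-Whitney p-value is exact (by
#' enumeration of the U null distribution) when the smaller sample has
#' at most 8 observations and there are no ties, and uses the normal
#' approximation with tie and continuity correction otherwise. Samples
#' too small or too large for the Shapiro-Wilk screen (n < 3 or
#' n > 5000) fall back to Mann-Whitney.
#'
#' @param a,b numeric samples, each of length >= 2, no missing values.
#' @param force_test `NULL` for automatic selection, or one of
#'   `"mann-whitney"`, `"t-two-sided"`.
#' @param alpha significance level for the final verdict (default 0.05).
#' @return An object of class `group_comparison`: list with `test`,
#'   `statistic` (U for Mann-Whitney, t otherwise), `p_two_sided`,
#'   `significant` (`p_two_sided < alpha`), `n_a`, `n_b`, `alpha`.
#' @examples
#' compare_groups(1:3, 4:6, force_test = "mann-whitney")  # U=0, P=0.1
#' @export
compare_groups <- function(a, b, force_test = NULL, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must have at least 2 observations")
  if (any(is.na(a)) || any(is.na(b)))
    stop("missing values must be excluded before comparison")
  if (is.null(force_test)) {
    looks_normal <- function(x) {
      n <- length(x)
      if (n < 3L || n > 5000L) return(FALSE)
      if (length(unique(x)) == 1L) return(FALSE)  # shapiro.test errors
      shapiro.test(x)$p.value > 0.05
    }
    test <- if (looks_normal(a) && looks_normal(b)) "t-two-sided"
            else "mann-whitney"
  } else {
    test <- match.arg(force_test, c("mann-whitney", "t-two-sided"))
  }
  if (test == "t-two-sided") {
    ht <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  } else {
    exact <- min(length(a), length(b)) <= 8L &&
             !any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE,
                  alternative = "two.sided"))
    # completely tied samples degenerate the normal approximation
    if (is.nan(ht$p.value)) ht$p.value <- 1
  }
  structure(
    list(test = test, statistic = unname(ht$statistic),
         p_two_sided = ht$p.value,
         significant = ht$p.value < alpha,
         n_a = length(a), n_b = length(b), alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g  P=%.4g  %s (alpha=%g, n=%d/%d)\n",
              x$test, x$statistic, x$p_two_sided,
              if (x$significant) "significant" else "not significant",
              x$alpha, x$n_a, x$n_b))
  invisible(x)
}

#' Feulgen-DNA C-class histogram
#'
#' Bins nuclear integrated absorbances (`A_T`, the Feulgen-DNA values)
#' into ploidy classes against a 2C anchor taken from a calibration
#' population (e.g. nuclei known to be diploid, or the control class
#' with the smallest values). The anchor is the median of the reference
#' — a robust stand-in for "the class containing the smallest values".
#' Class `~(2*2^k)C` spans `[anchor*2^(k-0.5), anchor*2^(k+0.5))` for
#' k = 0, 1, 2, ...: geometric midpoints between doubling classes.
#' Everything below `anchor/sqrt(2)` falls in `"<2C"` (subdiploid).
#' Every value maps to exactly one class, and class labels are invariant
#' under joint rescaling of values and reference.
#'
#' @param at_values numeric vector of A_T values, positive.
#' @param reference numeric vector of A_T values of the 2C calibration
#'   population, length >= 10.
#' @return An object of class `c_class_histogram`: list with
#'   `anchor_2C`, `labels`, `edges`, `counts`, `fractions`,
#'   `assignments` (factor parallel to `at_values`).
#' @examples
#' h <- c_class_histogram(c(70, 100, 200), reference = rep(100, 10))
#' h$assignments  # <2C, ~2C, ~4C
#' @export
c_class_histogram <- function(at_values, reference) {
  if (length(at_values) == 0L || length(reference) < 10L)
    stop("need at least 1 value and a reference population of >= 10")
  if (any(!is.finite(at_values)) || any(at_values <= 0) ||
      any(!is.finite(reference)) || any(reference <= 0))
    stop("A_T values must be positive and finite")
  anchor <- median(reference)
  kmax <- 1L
  while (max(at_values) >= anchor * 2^(kmax + 0.5)) kmax <- kmax + 1L
  edges <- anchor * 2^(seq(-0.5, kmax + 0.5, by = 1))
  labels <- c("<2C", paste0("~", 2^(seq_len(kmax + 1L)), "C"))
  bin <- findInterval(at_values, edges)  # 0 => "<2C"
  assignments <- factor(labels[bin + 1L], levels = labels)
  counts <- as.integer(table(assignments))
  structure(
    list(anchor_2C = anchor, labels = labels, edges = edges,
         counts = counts, fractions = counts / length(at_values),
         assignments = assignments),
    class = "c_class_histogram"
  )
}

#' @export
print.c_class_histogram <- function(x, ...) {
  cat(sprintf("c_class_histogram: anchor 2C = %.4g\n", x$anchor_2C))
  print(data.frame(label = x$labels, count = x$counts,
                   fraction = round(x$fractions, 4)))
  invisible(x)
}

#' @export
as.data.frame.c_class_histogram <- function(x, ...) {
  data.frame(label = x$labels, count = x$counts, fraction = x$fractions)
}

#' Sc% vs AAR phenotype scatter diagram
#'
#' The karyometric phenotype plane: each AAR-defined nucleus is a point
#' at (Sc%, AAR), colored by group. Chromatin decondensation moves
#' points left (lower condensed area) and up (higher contrast between
#' the remaining condensed foci and the whole nucleus). An optional
#' region map (`data.frame` with `label`, `sc_min`, `sc_max`, `aar_min`,
#' `aar_max`) can overlay named phenotype zones; none ships by default
#' since the zone geometry is a matter of laboratory convention.
#'
#' @param measurements data.frame with columns `Sc_pct` and `AAR` (e.g.
#'   rows of [measure_nuclei()]).
#' @param groups vector of group labels parallel to `measurements`
#'   rows (single label recycled).
#' @param regions optional phenotype-region data.frame (see above).
#' @return A list with `data` (the plotted points) and `plot` (a
#'   ggplot object).
#' @export
scatter_diagram <- function(measurements, groups = "all", regions = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("Sc_pct", "AAR") %in% names(measurements)))
  df <- data.frame(Sc_pct = measurements$Sc_pct, AAR = measurements$AAR,
                   group = rep_len(as.character(groups),
                                   nrow(measurements)))
  undef <- !is.finite(df$AAR)
  if (any(undef)) {
    message(sum(undef), " nuclei with undefined AAR omitted")
    df <- df[!undef, , drop = FALSE]
  }
  empty <- setdiff(unique(rep_len(as.character(groups),
                                  nrow(measurements))), df$group)
  if (length(empty))
    warning("group(s) with no AAR-defined nuclei omitted: ",
            paste(empty, collapse = ", "))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Sc_pct, y = .data$AAR,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "Sc% (relative condensed chromatin area)",
                  y = "AAR (average absorption ratio)",
                  colour = "group") +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE, alpha = 0.1,
      ggplot2::aes(xmin = .data$sc_min, xmax = .data$sc_max,
                   ymin = .data$aar_min, ymax = .data$aar_max)) +
      ggplot2::geom_text(
        data = regions, inherit.aes = FALSE, size = 3,
        ggplot2::aes(x = (.data$sc_min + .data$sc_max) / 2,
                     y = .data$aar_max, label = .data$label))
  }
  list(data = df, plot = p)
}

#' Cell classification counts
#'
#' Tally of visually scored cell classes over one preparation
#' (typically ~2000 Feulgen-stained cells): mitoses, abnormal mitoses,
#' micronucleated cells, giant nuclei, apoptotic cells and cell death
#' preceded by multinucleation. The pipeline consumes these as counts;
#' it does not detect the morphologies.
#'
#' @param total_cells total cells examined, >= 1.
#' @param mitoses,abnormal_mitoses,micronucleated,giant_nuclei,apoptotic,multinucleation_death
#'   class counts, each >= 0 and <= `total_cells`
#'   (`abnormal_mitoses <= mitoses`).
#' @return An object of class `cell_class_counts`.
#' @export
cell_class_counts <- function(total_cells, mitoses = 0,
                              abnormal_mitoses = 0, micronucleated = 0,
                              giant_nuclei = 0, apoptotic = 0,
                              multinucleation_death = 0) {
  cnt <- c(total_cells = total_cells, mitoses = mitoses,
           abnormal_mitoses = abnormal_mitoses,
           micronucleated = micronucleated, giant_nuclei = giant_nuclei,
           apoptotic = apoptotic,
           multinucleation_death = multinucleation_death)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (total_cells < 1) stop("`total_cells` must be >= 1")
  if (any(cnt[-1L] > total_cells))
    stop("class counts cannot exceed total_cells")
  if (abnormal_mitoses > mitoses)
    stop("`abnormal_mitoses` cannot exceed `mitoses`")
  structure(as.list(cnt), class = "cell_class_counts")
}

#' Mitotic and cell-death index ratios
#'
#' Expresses each scored class as a percentage of the cells examined
#' (the mitotic index being `100 * mitoses / total_cells`), and
#' additionally the abnormal mitoses as a percentage of all mitoses
#' (reported as `NA` when no mitosis was scored).
#'
#' @param counts a [cell_class_counts()].
#' @return data.frame with columns `measure`, `numerator`,
#'   `denominator`, `percent`.
#' @examples
#' index_ratios(cell_class_counts(2000, mitoses = 40))  # mitotic index 2%
#' @export
index_ratios <- function(counts) {
  stopifnot(inherits(counts, "cell_class_counts"))
  tot <- counts$total_cells
  of_total <- c(mitotic_index = counts$mitoses,
                abnormal_mitoses_pct = counts$abnormal_mitoses,
                micronucleated_pct = counts$micronucleated,
                giant_nuclei_pct = counts$giant_nuclei,
                apoptotic_pct = counts$apoptotic,
                multinucleation_death_pct = counts$multinucleation_death)
  df <- data.frame(measure = names(of_total),
                   numerator = unname(of_total), denominator = tot,
                   percent = 100 * unname(of_total) / tot)
  abn <- data.frame(
    measure = "abnormal_of_mitoses_pct",
    numerator = counts$abnormal_mitoses, denominator = counts$mitoses,
    percent = if (counts$mitoses > 0)
      100 * counts$abnormal_mitoses / counts$mitoses else NA_real_)
  rbind(df, abn)
}
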