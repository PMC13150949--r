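#' Mann--Whitney U test
#'
#' Rank-sum U statistic (for `x`) with midranks for ties. The two-sided
#' p-value is exact (from the null U distribution) when `n1 + n2 <= 12`
#' and the pooled sample has no ties; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `statistic`
#'   (U for `x`), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
mann_whitney_u <- function(x, y, labels = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- as.numeric(table(pooled))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= 12L) {
    # exact two-sided p from the null distribution of U
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - stats::pwilcox(u - 1, n1, n2))
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(
    group1 = labels[1], group2 = labels[2],
    n1 = n1, n2 = n2, statistic = u, p_value = p, method = method
  )
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for an explicit family size `m`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons in the family; must be at least
#'   `length(p_values)` and at least 1.
#' @return Numeric vector of adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m < length(p_values)) {
    stop("m must be at least the number of p-values in the family",
         call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Pairwise population comparisons of loop properties
#'
#' Runs a Mann--Whitney U test for each (property, population pair), with
#' Bonferroni correction whose family is the number of pairs tested for
#' that property (families are not pooled across properties).
#'
#' @param tbl Rearrangement tibble; property columns are derived with
#'   [annotate_physchem()] if absent.
#' @param properties Property columns to compare
#'   (default `c("loop_length", "net_charge", "gravy")`).
#' @param group_var Column holding the population label (default
#'   `"population"`). To compare genotypes within a population, pass a
#'   pre-filtered table and `group_var = "genotype"`.
#' @param pairs List of length-2 character vectors of group labels;
#'   default all pairs present.
#' @return A tibble: `property`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_populations <- function(tbl,
                                properties = c("loop_length", "net_charge",
                                               "gravy"),
                                group_var = "population",
                                pairs = NULL) {
  if (!group_var %in% names(tbl)) {
    stop("grouping column absent: ", group_var, call. = FALSE)
  }
  if (!all(properties %in% names(tbl))) {
    tbl <- annotate_physchem(tbl)
  }
  groups <- unique(tbl[[group_var]])
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(groups), 2L, simplify = FALSE)
  }
  unknown <- setdiff(unique(unlist(pairs)), groups)
  if (length(unknown) > 0L) {
    stop("unknown population label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- length(pairs)
  out <- purrr::map(properties, function(prop) {
    res <- purrr::map(pairs, function(pr) {
      xa <- tbl[[prop]][tbl[[group_var]] == pr[1]]
      xb <- tbl[[prop]][tbl[[group_var]] == pr[2]]
      dplyr::mutate(mann_whitney_u(xa, xb, labels = pr),
                    property = prop, .before = 1L)
    }) |> purrr::list_rbind()
    res$p_adjusted <- bonferroni(res$p_value, m = m)
    res
  }) |> purrr::list_rbind()
  out$method <- NULL
  out
}

#' PCA of population-mean descriptor profiles
#'
#' Principal component analysis of the small matrix of population-mean
#' six-factor profiles (one row per population), as column-centred
#' covariance PCA via [stats::prcomp]. Columns are not scaled to unit
#' variance by default (the descriptors are already standardised scales);
#' set `scale.` to change that. Components are ordered by decreasing
#' variance and signed so that each loading vector's largest-magnitude
#' element is positive, making scores reproducible across platforms.
#'
#' @param profiles A tibble as from [population_profiles()] (factor
#'   columns `F1` ... `F6` are used, label columns kept as row labels), or
#'   a plain numeric matrix with at least 2 rows.
#' @param scale. Scale columns to unit variance before decomposition
#'   (default `FALSE`).
#' @return An object of class `hcdr3_pca`: list with `scores` (tibble with
#'   label columns and `PC1` ...), `loadings` (matrix, variables x
#'   components), `variance_fraction`, `sdev`, `center`, `scale`.
#' @export
pca_profiles <- function(profiles, scale. = FALSE) {
  if (is.matrix(profiles)) {
    m <- profiles
    labels <- tibble::tibble(row = rownames(m) %||% as.character(seq_len(nrow(m))))
  } else {
    fac_cols <- intersect(c(paste0("F", 1:6)), names(profiles))
    if (length(fac_cols) == 0L) {
      fac_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
    }
    m <- as.matrix(profiles[, fac_cols])
    labels <- profiles[, setdiff(names(profiles), fac_cols), drop = FALSE]
    labels <- labels[, !vapply(labels, is.numeric, logical(1)), drop = FALSE]
  }
  if (nrow(m) < 2L) stop("at least 2 rows (populations) required", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  total_var <- sum(pc$sdev^2)
  if (total_var < .Machine$double.eps) {
    warning("zero-variance input; variance fractions set to 0", call. = FALSE)
    vf <- rep(0, length(pc$sdev))
  } else {
    vf <- pc$sdev^2 / total_var
  }
  # deterministic sign: largest-magnitude loading element positive
  for (k in seq_len(ncol(pc$rotation))) {
    v <- pc$rotation[, k]
    if (v[which.max(abs(v))] < 0) {
      pc$rotation[, k] <- -v
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- dplyr::bind_cols(labels, tibble::as_tibble(pc$x))
  structure(
    list(
      scores = scores,
      loadings = pc$rotation,
      variance_fraction = stats::setNames(vf, colnames(pc$rotation)),
      sdev = pc$sdev,
      center = pc$center,
      scale = pc$scale
    ),
    class = "hcdr3_pca"
  )
}

#' @exportS3Method generics::tidy
tidy.hcdr3_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.hcdr3_pca <- function(x, ...) {
  tibble::tibble(
    component = names(x$variance_fraction),
    sdev = x$sdev,
    variance_fraction = unname(x$variance_fraction)
  )
}

#' @export
print.hcdr3_pca <- function(x, ...) {
  cat("PCA of population-mean profiles\n")
  cat("variance fractions:",
      paste(sprintf("%s=%.3f", names(x$variance_fraction),
                    x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hcdr3_pca <- function(object, label_col = NULL, ...) {
  scores <- object$scores
  if (is.null(label_col)) {
    lab_cols <- names(scores)[!vapply(scores, is.numeric, logical(1))]
    label_col <- if (length(lab_cols) > 0) lab_cols[1] else NULL
  }
  vf <- object$variance_fraction
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[["PC1"]]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[["PC2"]])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(label_col)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data[[label_col]]),
      vjust = -0.8, size = 3
    )
  }
  p
}
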