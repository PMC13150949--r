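# Worst aspect ratio of a row of areas laid along a side of given length.
.worst_aspect <- function(row, side) {
  s <- sum(row)
  t <- s / side
  len <- row / t
  max(pmax(t / len, len / t))
}

#' Squarified treemap layout of a clonal stratification
#'
#' Lays one rectangle per clone on a canvas, area exactly proportional to
#' clone size, using the squarified treemap algorithm (rows packed along
#' the shorter side of the remaining rectangle, greedily keeping tile
#' aspect ratios close to 1). Clones are taken in the stratification's
#' deterministic order (descending size, ties lexicographic), so the
#' layout is reproducible.
#'
#' @param strat Stratification from [group_clones()] (categories kept if
#'   present).
#' @param width,height Canvas dimensions in arbitrary units (areas > 0).
#' @return A tibble with one row per clone: `clone_id`, key columns,
#'   `category` (if present), `n`, and rectangle `x`, `y`, `w`, `h`
#'   (origin bottom-left).
#' @export
treemap_layout <- function(strat, width = 100, height = 100) {
  stopifnot(inherits(strat, "hcdr3_strat"))
  if (width <= 0 || height <= 0) stop("canvas area must be positive", call. = FALSE)
  total <- attr(strat, "total_sequences")
  areas <- strat$n / total * (width * height)
  k <- length(areas)
  x <- y <- w <- h <- numeric(k)
  rx <- 0; ry <- 0; rw <- width; rh <- height
  i <- 1L
  while (i <= k) {
    side <- min(rw, rh)
    j <- i
    worst <- .worst_aspect(areas[i], side)
    while (j < k) {
      cand <- .worst_aspect(areas[i:(j + 1L)], side)
      if (cand <= worst) {
        worst <- cand
        j <- j + 1L
      } else {
        break
      }
    }
    row <- areas[i:j]
    t <- sum(row) / side
    off <- 0
    if (rw >= rh) {
      # vertical strip of thickness t on the left edge
      for (m in seq_along(row)) {
        idx <- i + m - 1L
        x[idx] <- rx; y[idx] <- ry + off
        w[idx] <- t; h[idx] <- row[m] / t
        off <- off + h[idx]
      }
      rx <- rx + t; rw <- rw - t
    } else {
      # horizontal strip of thickness t on the bottom edge
      for (m in seq_along(row)) {
        idx <- i + m - 1L
        x[idx] <- rx + off; y[idx] <- ry
        w[idx] <- row[m] / t; h[idx] <- t
        off <- off + w[idx]
      }
      ry <- ry + t; rh <- rh - t
    }
    i <- j + 1L
  }
  cols <- unname(.key_columns[attr(strat, "key_fields")])
  keep <- c("clone_id", cols, intersect("category", names(strat)), "n")
  out <- tibble::as_tibble(strat)[, keep]
  out$x <- x; out$y <- y; out$w <- w; out$h <- h
  attr(out, "canvas") <- c(width = width, height = height)
  out
}

#' Write a treemap layout as a standalone SVG file
#'
#' @param layout Tibble from [treemap_layout()].
#' @param path Output path.
#' @param fill Named vector of fill colours per category.
#' @return Invisibly, `path`.
#' @export
treemap_svg <- function(layout, path,
                        fill = c(single = "#c6dbef",
                                 expanded_lt1 = "#6baed6",
                                 highly_expanded = "#08519c")) {
  canvas <- attr(layout, "canvas")
  cat_col <- if ("category" %in% names(layout)) {
    unname(fill[as.character(layout$category)])
  } else {
    rep("#6baed6", nrow(layout))
  }
  cat_col[is.na(cat_col)] <- "#999999"
  # SVG y axis points down; flip so layout origin is bottom-left
  rects <- sprintf(
    '  <rect x="%.6f" y="%.6f" width="%.6f" height="%.6f" fill="%s" stroke="white" stroke-width="0.2"/>',
    layout$x, canvas[["height"]] - layout$y - layout$h,
    layout$w, layout$h, cat_col
  )
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %.2f %.2f">',
            canvas[["width"]], canvas[["height"]]),
    rects,
    "</svg>"
  ), path)
  invisible(path)
}

#' Plot a clonal landscape treemap
#'
#' @param strat Stratification (classified with [classify_expansion()] for
#'   category colours).
#' @param width,height Canvas dimensions.
#' @return A ggplot object.
#' @export
plot_treemap <- function(strat, width = 100, height = 100) {
  layout <- treemap_layout(strat, width = width, height = height)
  has_cat <- "category" %in% names(layout)
  mapping <- ggplot2::aes(
    xmin = .data$x, xmax = .data$x + .data$w,
    ymin = .data$y, ymax = .data$y + .data$h
  )
  p <- ggplot2::ggplot(layout, mapping)
  p <- if (has_cat) {
    p + ggplot2::geom_rect(ggplot2::aes(fill = .data$category),
                           colour = "white", linewidth = 0.2) +
      ggplot2::scale_fill_manual(values = c(
        single = "#c6dbef", expanded_lt1 = "#6baed6",
        highly_expanded = "#08519c"
      ))
  } else {
    p + ggplot2::geom_rect(fill = "#6baed6", colour = "white",
                           linewidth = 0.2)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hcdr3_strat <- function(object, ...) plot_treemap(object, ...)
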