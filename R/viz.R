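# -- Manhattan plot + distribution plots ---------------------------------------
#
# Coordinate computation (testable, render-free) is kept strictly separate
# from rendering. Raw p-values are plotted as -log10(p); multiple-testing
# correction enters only through the threshold lines.

#' Map variables to exposure categories
#'
#' @param variable Character vector of variable names.
#' @param category Parallel vector of category labels.
#' @return A `category_map` data frame; variables absent from the map plot
#'   under category `"unknown"`, ordered last.
#' @export
category_map <- function(variable = character(), category = character()) {
  m <- data.frame(variable = as.character(variable),
                  category = as.character(category),
                  stringsAsFactors = FALSE)
  dup <- unique(m$variable[duplicated(m$variable)])
  if (length(dup)) {
    stop("variable(s) mapped twice: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  class(m) <- c("category_map", class(m))
  m
}

#' @rdname category_map
#' @param path TSV with columns `variable`, `category`.
#' @param delimiter Field separator.
#' @export
read_category_map <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("variable", "category") %in% names(df))) {
    stop("category map needs columns 'variable' and 'category'",
         call. = FALSE)
  }
  category_map(df$variable, df$category)
}

#' Compute Manhattan-plot coordinates for EWAS results
#'
#' Groups variables into category blocks (categories sorted, `"unknown"`
#' last; variables sorted by name within a block) and assigns contiguous
#' integer x positions shared across datasets, with `y = -log10(p)` of each
#' row's raw p-value. Rows without a computed p-value are excluded. Per
#' dataset, a Bonferroni threshold line is placed at
#' `-log10(alpha / m_dataset)` and, when any test passes the BH gate, an FDR
#' line at the largest passing raw p. Variables crossing the Bonferroni
#' threshold in *every* dataset they appear in are flagged for text labels.
#'
#' @param results An `ewas_result` or a named list of them (names become
#'   dataset labels, e.g. `Discovery` / `Replication`).
#' @param categories Optional [category_map()].
#' @param bonferroni_alpha Family-wise alpha for the red threshold line
#'   (default 0.05).
#' @param fdr_alpha FDR level for the optional second line (default 0.10).
#' @param label_below `"bonferroni"` (default), `"fdr"`, or `"none"` —
#'   which threshold flags rows for labeling.
#' @param y_cap Cap for `-log10(p)` when p underflows to 0 (default 320).
#' @return List with `points` (variable, category, x, y, dataset, marker,
#'   label, capped) and `thresholds` (dataset, type, alpha, m, y).
#' @export
manhattan_coordinates <- function(results, categories = NULL,
                                  bonferroni_alpha = 0.05, fdr_alpha = 0.10,
                                  label_below = c("bonferroni", "fdr",
                                                  "none"),
                                  y_cap = 320) {
  label_below <- match.arg(label_below)
  if (inherits(results, "ewas_result")) results <- list(results = results)
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("dataset", seq_along(results))
  }

  long <- do.call(rbind, lapply(names(results), function(ds) {
    r <- results[[ds]]
    p <- raw_pvalues(r)
    ok <- !is.na(p)
    data.frame(variable = r$variable[ok], p = p[ok], dataset = ds,
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) {
    stop("no computed p-values to plot", call. = FALSE)
  }

  cat_of <- function(v) {
    if (is.null(categories)) return(rep("unknown", length(v)))
    i <- match(v, categories$variable)
    ifelse(is.na(i), "unknown", categories$category[i])
  }
  vars <- sort(unique(long$variable))
  vcat <- cat_of(vars)
  cats <- c(sort(setdiff(unique(vcat), "unknown")),
            if ("unknown" %in% vcat) "unknown")
  ord <- order(match(vcat, cats), vars)
  xpos <- stats::setNames(seq_along(vars), vars[ord])

  thresholds <- do.call(rbind, lapply(names(results), function(ds) {
    pd <- long$p[long$dataset == ds]
    m <- length(pd)
    bonf <- data.frame(dataset = ds, type = "bonferroni",
                       alpha = bonferroni_alpha, m = m,
                       y = -log10(bonferroni_alpha / m),
                       stringsAsFactors = FALSE)
    qd <- stats::p.adjust(pd, method = "BH")
    if (any(qd <= fdr_alpha)) {
      fdr <- data.frame(dataset = ds, type = "fdr", alpha = fdr_alpha,
                        m = m, y = -log10(max(pd[qd <= fdr_alpha])),
                        stringsAsFactors = FALSE)
      rbind(bonf, fdr)
    } else bonf
  }))

  pass <- function(row_var, row_p, ds) {
    m <- thresholds$m[thresholds$dataset == ds &
                        thresholds$type == "bonferroni"]
    switch(label_below,
           bonferroni = row_p <= bonferroni_alpha / m,
           fdr = {
             pd <- long$p[long$dataset == ds]
             qd <- stats::p.adjust(pd, method = "BH")
             any(qd <= fdr_alpha) && row_p <= max(pd[qd <= fdr_alpha])
           },
           none = FALSE)
  }
  hit <- mapply(pass, long$variable, long$p, long$dataset)
  label_vars <- if (label_below == "none") character() else {
    Filter(function(v) all(hit[long$variable == v]), unique(long$variable))
  }

  y <- -log10(long$p)
  capped <- !is.finite(y) | y > y_cap
  y[capped] <- y_cap
  markers <- stats::setNames(seq_along(results), names(results))
  points <- data.frame(variable = long$variable,
                       category = cat_of(long$variable),
                       x = unname(xpos[long$variable]),
                       y = y, dataset = long$dataset,
                       marker = unname(markers[long$dataset]),
                       label = long$variable %in% label_vars,
                       capped = capped,
                       stringsAsFactors = FALSE)
  points <- points[order(points$x, points$dataset), , drop = FALSE]
  rownames(points) <- NULL
  list(points = points, thresholds = thresholds)
}

#' Render a Manhattan plot from precomputed coordinates
#'
#' Pure rendering: draws the `points` and `thresholds` of
#' [manhattan_coordinates()] without computing any statistics. Marker shape
#' distinguishes datasets, color distinguishes categories, horizontal lines
#' mark the thresholds, and label-flagged points get text labels. The output
#' device is chosen by file extension (`.png` or `.svg`).
#'
#' @param table Output of [manhattan_coordinates()].
#' @param path Output image path.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG output.
#' @return The path, invisibly.
#' @export
render_manhattan <- function(table, path, width = 10, height = 5,
                             dpi = 150) {
  pts <- table$points
  if (is.null(pts) || nrow(pts) == 0) stop("empty Manhattan table",
                                           call. = FALSE)
  mids <- vapply(split(pts$x, pts$category), stats::median, numeric(1))
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         color = .data$category,
                                         shape = .data$dataset)) +
    ggplot2::geom_hline(data = table$thresholds,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$dataset),
                        color = ifelse(table$thresholds$type == "bonferroni",
                                       "red", "blue")) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_text(data = pts[pts$label & !duplicated(pts$variable), ],
                       ggplot2::aes(label = .data$variable),
                       size = 2.3, vjust = -0.8, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = unname(mids),
                                labels = names(mids)) +
    ggplot2::labs(x = "exposure category", y = expression(-log[10](p))) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  save_plot_file(g, path, width, height, dpi)
}

save_plot_file <- function(g, path, width, height, dpi) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(g)
  invisible(path)
}

#' High-throughput per-variable distribution plots
#'
#' Writes one image per variable: histograms for continuous variables
#' (optionally with a boxplot panel) and bar charts for binary/categorical
#' variables. Variables typed `check` are drawn as bar charts of their
#' distinct values; all-missing variables are skipped with a warning.
#'
#' @param typed A `typed_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param bins Histogram bin count (default 30).
#' @param width,height,dpi Device parameters.
#' @return Invisibly, the written file paths (named by variable).
#' @export
distribution_plots <- function(typed, out_dir, format = c("png", "svg"),
                               bins = 30, width = 5, height = 4, dpi = 120) {
  format <- match.arg(format)
  stopifnot(inherits(typed, "typed_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (v in variable_names(typed)) {
    type <- typed$types[[v]]
    tokens <- typed$data$values[[v]]
    if (all(is.na(tokens))) {
      warning("variable '", v, "' is all-missing; skipped", call. = FALSE)
      next
    }
    path <- file.path(out_dir, paste0(v, ".", format))
    if (type == "continuous") {
      x <- variable_values(typed$data, v, as = "numeric", quiet = TRUE)
      df <- data.frame(x = x[!is.na(x)])
      g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
        ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                                color = "white") +
        ggplot2::labs(x = v, y = "count") +
        ggplot2::theme_minimal()
    } else {
      df <- data.frame(level = tokens[!is.na(tokens)])
      g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$level)) +
        ggplot2::geom_bar(fill = "steelblue") +
        ggplot2::labs(x = v, y = "count") +
        ggplot2::theme_minimal()
    }
    save_plot_file(g, path, width, height, dpi)
    paths[v] <- path
  }
  invisible(paths)
}
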