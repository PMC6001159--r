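#' Boolean process map
#'
#' One row per process, grouped by variable: a filled bar segment where the
#' process is active, blank where inactive.  Alongside the image a companion
#' CSV of the plotted segments is written, and the figure's correctness is
#' tested on that table, never on pixels.
#'
#' @param activity a `ppa_activity`.
#' @param path image file (`.png` or `.svg`).
#' @param title plot title.
#' @return Invisibly, the data frame of active segments
#'   (`process`, `variable`, `from`, `to`).
#' @export
render_boolean_map <- function(activity, path, title = "Boolean process map") {
  if (!ncol(activity$active)) stop("empty activity profile")
  tt <- activity$times
  labs <- colnames(activity$active)
  segs <- list()
  for (j in seq_along(labs)) {
    a <- activity$active[, j]
    r <- rle(a)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    on <- which(r$values)
    if (length(on))
      segs[[j]] <- data.frame(process = labs[j],
                              variable = activity$variables[activity$var_of[j]],
                              from = tt[starts[on]], to = tt[ends[on]])
  }
  segdf <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  open_device(path, width = 7, height = 10)
  on.exit(grDevices::dev.off())
  np <- length(labs)
  graphics::plot(NULL, xlim = range(tt), ylim = c(0, np + 1),
                 xlab = "time (h)", ylab = "", yaxt = "n", main = title)
  graphics::axis(2, at = np - seq_along(labs) + 1, labels = labs,
                 las = 2, cex.axis = 0.4)
  for (r in seq_len(nrow(segdf))) {
    j <- match(segdf$process[r], labs)
    y <- np - j + 1
    graphics::rect(segdf$from[r], y - 0.4, segdf$to[r], y + 0.4,
                   col = "black", border = NA)
  }
  utils::write.csv(segdf, companion_csv(path), row.names = FALSE, quote = FALSE)
  invisible(segdf)
}

#' Dynamical process map
#'
#' Network view of one time window: variables are nodes; every process is an
#' arrow into the variable whose equation it belongs to, coloured by the
#' window's activity of the *biochemical* process it represents: red when
#' active in every equation sharing it, black when inactive in all, yellow
#' when mixed.  Requires the igraph package; layout is deterministic
#' (circular).
#'
#' @param model a [process_model()] with links declared.
#' @param window_mask named logical vector over process labels: active in
#'   the window?  (e.g. a schedule mask, or an activity snapshot).
#' @param path image file.
#' @return Invisibly, the edge table (`process`, `from`, `to`, `colour`).
#' @export
render_dynamical_map <- function(model, window_mask, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("render_dynamical_map() needs the igraph package")
  labs <- model$labels
  stopifnot(all(labs %in% names(window_mask)))
  link_of <- stats::setNames(rep(NA_integer_, length(labs)), labs)
  for (li in seq_along(model$links)) link_of[model$links[[li]]] <- li
  colour_of <- function(lab) {
    members <- if (is.na(link_of[lab])) lab
               else model$links[[link_of[lab]]]
    st <- window_mask[members]
    if (all(st)) "red" else if (all(!st)) "black" else "yellow"
  }
  var_of <- rep(seq_along(model$terms), lengths(model$terms))
  src_of <- function(lab) {
    i <- var_of[match(lab, labs)]
    trm <- unlist(model$terms, recursive = FALSE)[[match(lab, labs)]]
    v <- intersect(all.vars(trm$expr), model$variables)
    v <- setdiff(v, model$variables[i])
    if (length(v)) v[1] else model$variables[i]
  }
  edges <- data.frame(
    process = labs,
    from = vapply(labs, src_of, ""),
    to = model$variables[var_of],
    colour = vapply(labs, colour_of, ""))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = model$variables)
  open_device(path, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    edge.color = edges$colour, edge.arrow.size = 0.3,
    vertex.color = "grey90", vertex.label.cex = 0.8,
    vertex.size = 18)
  utils::write.csv(edges, companion_csv(path), row.names = FALSE, quote = FALSE)
  invisible(edges)
}

#' Hourly-binned process-weight map
#'
#' The "3-D" view of one variable's equation: per process and per hour, the
#' trapezoidal mean of the weight over the hour, drawn as grouped bars whose
#' colour intensity scales linearly with the weight (normalised within the
#' variable).
#'
#' @param weights a `ppa_weights`.
#' @param variable variable name or index.
#' @param path image file.
#' @param bin bin width in hours (must divide the horizon).
#' @return Invisibly, the matrix of hourly mean weights (bins x processes).
#' @export
render_3d_map <- function(weights, variable, path, bin = 1) {
  if (is.character(variable)) variable <- match(variable, weights$variables)
  stopifnot(!is.na(variable))
  tt <- weights$times
  span <- tt[length(tt)] - tt[1]
  if (span < bin) stop("horizon shorter than one bin")
  cols <- which(weights$var_of == variable)
  edges <- seq(tt[1], tt[length(tt)], by = bin)
  if (abs(edges[length(edges)] - tt[length(tt)]) > 1e-9)
    stop("bin width must divide the horizon")
  nb <- length(edges) - 1
  M <- matrix(NA_real_, nb, length(cols),
              dimnames = list(sprintf("h%02d", seq_len(nb) - 1),
                              colnames(weights$W)[cols]))
  for (b in seq_len(nb)) {
    sel <- tt >= edges[b] & tt <= edges[b + 1]
    ts <- tt[sel]
    for (q in seq_along(cols)) {
      y <- weights$W[sel, cols[q]]
      M[b, q] <- sum(diff(ts) * (y[-length(y)] + y[-1]) / 2) / (ts[length(ts)] - ts[1])
    }
  }
  open_device(path, width = 9, height = 5)
  on.exit(grDevices::dev.off())
  rel <- if (max(M) > 0) M / max(M) else M
  colmat <- grDevices::rgb(1 - rel * 0.9, 1 - rel * 0.9, 1)
  graphics::barplot(t(M), beside = TRUE, col = t(colmat),
                    names.arg = rownames(M), las = 2, cex.names = 0.7,
                    ylab = "mean weight",
                    main = sprintf("Hourly process weights: %s",
                                   weights$variables[variable]))
  graphics::legend("topright", legend = colnames(M), fill = "grey70",
                   cex = 0.6, bty = "n")
  utils::write.csv(data.frame(bin = rownames(M), M, check.names = FALSE),
                   companion_csv(path), row.names = FALSE, quote = FALSE)
  invisible(M)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100, height = height * 100),
         stop("unsupported image format: ", ext))
}

companion_csv <- function(path) paste0(tools::file_path_sans_ext(path), ".csv")
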