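# Connected-component labeling of binary masks, re-implementing the
# area-measurement step of the ImageJ-based workflow. Run-based two-pass
# union-find: contiguous TRUE runs per row are the primitive, runs in
# adjacent rows are merged when their column spans touch. 8-connectivity
# lets runs touch diagonally (spans overlapping within +/- 1 column).

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return An integer matrix of the same shape: 0 for background, components
#'   numbered 1..n in first-encounter order.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(labelComponents(m))            # diagonal touch: one component
#' max(labelComponents(m, 4))        # 4-connected: two components
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask),
            connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)

  # runs per row: list of (start_col, end_col, run_id)
  runs <- vector("list", nr)
  nRuns <- 0L
  for (i in seq_len(nr)) {
    row <- mask[i, ]
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    s <- starts[keep]; e <- ends[keep]
    ids <- nRuns + seq_along(s)
    nRuns <- nRuns + length(s)
    runs[[i]] <- cbind(start = s, end = e, id = ids)
  }

  parent <- seq_len(nRuns)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  slack <- if (connectivity == 8) 1L else 0L
  for (i in seq_len(nr)[-1]) {
    cur <- runs[[i]]; prev <- runs[[i - 1L]]
    if (is.null(cur) || is.null(prev)) next
    for (j in seq_len(nrow(cur))) {
      touch <- prev[, "start"] <= cur[j, "end"] + slack &
               prev[, "end"] >= cur[j, "start"] - slack
      for (k in which(touch)) unite(cur[j, "id"], prev[k, "id"])
    }
  }

  root <- vapply(seq_len(nRuns), findRoot, integer(1))
  lab <- match(root, unique(root))
  for (i in seq_len(nr)) {
    if (is.null(runs[[i]])) next
    ri <- runs[[i]]
    for (j in seq_len(nrow(ri)))
      out[i, ri[j, "start"]:ri[j, "end"]] <- lab[ri[j, "id"]]
  }
  out
}
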