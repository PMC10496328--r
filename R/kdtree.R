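# Balanced 3D kd-tree over atom coordinates: the performance core of
# interaction detection. The tree is static -- built once per model --
# and queried with closed-ball radius searches so that "distance <=
# threshold" bond criteria map one-to-one onto queries.
#
# Determinism: splits take the lower median on even counts; coordinate
# ties are broken by the smaller id, so identical input always yields an
# identical tree shape. Axis cycles x -> y -> z with depth.

# package-global accumulator so candidate work inside detectors (which
# build their indexes internally) can be measured across a pipeline run
.eval_total <- new.env(parent = emptyenv())
.eval_total$n <- 0

#' Global candidate-evaluation counter
#'
#' Sum of candidate evaluations over every query on every index since the
#' last reset; used to demonstrate sub-quadratic scaling of detection.
#'
#' @return Total number of point-against-center distance evaluations.
#' @export
eval_counter_total <- function() .eval_total$n

#' @rdname eval_counter_total
#' @export
eval_counter_reset <- function() {
  .eval_total$n <- 0
  invisible(NULL)
}

#' Build a balanced 3D spatial index
#'
#' @param coords Numeric matrix, one row per point, 3 columns (Angstroms).
#'   All coordinates must be finite. Zero rows give a valid empty index.
#' @param ids Vector of unique identifiers, one per row; defaults to the
#'   row numbers. Ties (duplicate coordinates, median ties) are broken by
#'   ordering on `ids`.
#' @return An object of class `kd_index`.
#' @export
build_index <- function(coords, ids = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0L, 3L)
  if (ncol(coords) != 3L) stop("build_index: coords must have 3 columns", call. = FALSE)
  if (!all(is.finite(coords))) stop("build_index: non-finite coordinates", call. = FALSE)
  n <- nrow(coords)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("build_index: length(ids) != nrow(coords)", call. = FALSE)
  if (anyDuplicated(ids)) stop("build_index: ids must be unique", call. = FALSE)

  # nodes stored in preallocated arrays; children as indices (0 = leaf end)
  pt <- integer(n)     # row index of the point at this node
  ax <- integer(n)     # split axis 1..3
  lft <- integer(n)
  rgt <- integer(n)
  nxt <- 0L

  # rank of ids for deterministic tie-breaks even with character ids
  id_rank <- rank(ids, ties.method = "first")

  build <- function(rows, depth) {
    m <- length(rows)
    if (m == 0L) return(0L)
    axis <- (depth %% 3L) + 1L
    ord <- order(coords[rows, axis], id_rank[rows])
    rows <- rows[ord]
    med <- (m + 1L) %/% 2L  # lower median on even counts
    nxt <<- nxt + 1L
    node <- nxt
    pt[node] <<- rows[med]
    ax[node] <<- axis
    lft[node] <<- build(rows[seq_len(med - 1L)], depth + 1L)
    rgt[node] <<- if (med < m) build(rows[(med + 1L):m], depth + 1L) else 0L
    node
  }
  root <- if (n > 0L) build(seq_len(n), 0L) else 0L

  stats <- new.env(parent = emptyenv())
  stats$evals <- 0

  structure(
    list(coords = coords, ids = ids, pt = pt, ax = ax, lft = lft, rgt = rgt,
         root = root, size = n, stats = stats),
    class = "kd_index"
  )
}

#' @export
print.kd_index <- function(x, ...) {
  cat(sprintf("<kd_index: %d points, depth %d>\n", x$size, index_depth(x)))
  invisible(x)
}

#' Depth of a spatial index
#'
#' Number of levels in the partition tree (a single node has depth 1, the
#' empty index depth 0). Balance guarantee: depth `<= ceiling(log2(n)) + 1`.
#'
#' @param index A `kd_index`.
#' @return Integer depth.
#' @export
index_depth <- function(index) {
  if (index$root == 0L) return(0L)
  lft <- index$lft; rgt <- index$rgt
  depth_of <- function(node) {
    if (node == 0L) return(0L)
    1L + max(depth_of(lft[node]), depth_of(rgt[node]))
  }
  depth_of(index$root)
}

#' Radius query (closed ball)
#'
#' Returns the ids of all indexed points whose Euclidean distance from
#' `center` is `<= r` -- the boundary is inclusive, matching the closed
#' comparisons used by every bond criterion.
#'
#' @param index A `kd_index`.
#' @param center Numeric 3-vector.
#' @param r Radius in Angstroms, `>= 0`.
#' @return Vector of ids (possibly empty), in no particular order.
#' @export
query_radius <- function(index, center, r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("query_radius: r must be a single non-negative number", call. = FALSE)
  if (index$root == 0L) return(index$ids[0L])
  coords <- index$coords; pt <- index$pt; ax <- index$ax
  lft <- index$lft; rgt <- index$rgt
  r2 <- r * r
  hits <- integer(0)
  evals <- 0L
  # iterative traversal with an explicit stack (avoids deep recursion)
  stack <- integer(64L)
  stack[1L] <- index$root
  top <- 1L
  while (top > 0L) {
    node <- stack[top]; top <- top - 1L
    row <- pt[node]
    d <- coords[row, ] - center
    evals <- evals + 1L
    if (sum(d * d) <= r2) hits <- c(hits, row)
    axis <- ax[node]
    delta <- center[axis] - coords[row, axis]
    if (top + 2L > length(stack)) stack <- c(stack, integer(length(stack)))
    if (delta <= r && lft[node] != 0L) { top <- top + 1L; stack[top] <- lft[node] }
    if (delta >= -r && rgt[node] != 0L) { top <- top + 1L; stack[top] <- rgt[node] }
  }
  index$stats$evals <- index$stats$evals + evals
  .eval_total$n <- .eval_total$n + evals
  index$ids[hits]
}

#' Nearest-neighbour query
#'
#' Returns the indexed point at globally minimal distance from `center`;
#' exact distance ties are broken by the smaller id.
#'
#' @param index A non-empty `kd_index`.
#' @param center Numeric 3-vector.
#' @return List with `id` and `distance`.
#' @export
query_nearest <- function(index, center) {
  if (index$root == 0L) stop("query_nearest: empty index", call. = FALSE)
  coords <- index$coords; pt <- index$pt; ax <- index$ax
  lft <- index$lft; rgt <- index$rgt
  id_rank <- rank(index$ids, ties.method = "first")
  best_d2 <- Inf
  best_row <- 0L
  evals <- 0L
  visit <- function(node) {
    if (node == 0L) return(invisible())
    row <- pt[node]
    d <- coords[row, ] - center
    d2 <- sum(d * d)
    evals <<- evals + 1L
    if (d2 < best_d2 ||
        (d2 == best_d2 && best_row != 0L && id_rank[row] < id_rank[best_row])) {
      best_d2 <<- d2
      best_row <<- row
    }
    axis <- ax[node]
    delta <- center[axis] - coords[row, axis]
    near <- if (delta < 0) lft[node] else rgt[node]
    far <- if (delta < 0) rgt[node] else lft[node]
    visit(near)
    if (delta * delta <= best_d2) visit(far)  # <=: far side may hold an id-tie
    invisible()
  }
  visit(index$root)
  index$stats$evals <- index$stats$evals + evals
  list(id = index$ids[best_row], distance = sqrt(best_d2))
}

#' Candidate-evaluation counter
#'
#' Each point actually compared against a query center counts as one
#' candidate evaluation. The counter accumulates across queries on the
#' same index and underpins the sub-quadratic scaling check.
#'
#' @param index A `kd_index`.
#' @return Number of evaluations since the index was built or last reset.
#' @export
index_eval_count <- function(index) index$stats$evals

#' @rdname index_eval_count
#' @export
reset_eval_count <- function(index) {
  index$stats$evals <- 0
  invisible(index)
}
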