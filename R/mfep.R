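# Minimum free-energy paths on 2D grids: global minimax criterion with
# deterministic tie-breaks, 8-connected moves, periodic-aware.

# Neighbour offsets for 8-connectivity.
.moves <- cbind(
  di = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dj = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# Neighbours of node (i, j) on an n1 x n2 grid; periodic wrap per axis.
.grid_neighbors <- function(i, j, n1, n2, per1, per2) {
  ii <- i + .moves[, 1]
  jj <- j + .moves[, 2]
  if (per1) ii <- ((ii - 1) %% n1) + 1
  if (per2) jj <- ((jj - 1) %% n2) + 1
  keep <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
  cbind(ii[keep], jj[keep])
}

# Precompute the neighbour id list for every node (linear ids, column-major).
.neighbor_ids <- function(n1, n2, per1, per2) {
  out <- vector("list", n1 * n2)
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      nb <- .grid_neighbors(i, j, n1, n2, per1, per2)
      out[[i + (j - 1) * n1]] <- nb[, 1] + (nb[, 2] - 1) * n1
    }
  }
  out
}

#' Locate free-energy basins on a grid
#'
#' Finds all strict local minima under 8-connectivity (periodic-aware) and
#' filters them by basin depth: a minimum is kept when the lowest saddle
#' connecting it to any deeper basin lies more than `depth_threshold`
#' kcal/mol above it (a persistence sweep over nodes in increasing energy
#' order).  The global minimum always survives.
#'
#' @param fes an `fes_grid`.
#' @param depth_threshold minimum basin depth, kcal/mol.
#' @return tibble of basins sorted by free energy: grid indices `i`, `j`,
#'   coordinates (axis names), `free_energy`, `depth` (Inf for the global
#'   minimum).  A flat grid yields zero rows.
#' @export
find_minima <- function(fes, depth_threshold = 0) {
  F <- fes$values
  n1 <- nrow(F); n2 <- ncol(F)
  per1 <- fes$axes[[1]]$periodic; per2 <- fes$axes[[2]]$periodic
  nb <- .neighbor_ids(n1, n2, per1, per2)
  Fv <- as.vector(F)

  is_min <- vapply(seq_along(Fv), function(v) all(Fv[v] < Fv[nb[[v]]]),
                   logical(1))
  if (!any(is_min)) {
    return(tibble(i = integer(), j = integer(),
                  !!fes$axes[[1]]$name := numeric(),
                  !!fes$axes[[2]]$name := numeric(),
                  free_energy = numeric(), depth = numeric()))
  }

  ord <- order(Fv)
  rank_of <- integer(length(Fv)); rank_of[ord] <- seq_along(ord)
  comp <- integer(length(Fv))          # 0 = not yet processed
  comp_min <- numeric(0)
  comp_minid <- integer(0)
  members <- list()
  depth <- rep(Inf, length(Fv))

  for (v in ord) {
    nbc <- unique(comp[nb[[v]]])
    nbc <- nbc[nbc > 0]
    if (length(nbc) == 0) {
      k <- length(members) + 1L
      comp[v] <- k
      comp_min[k] <- Fv[v]
      comp_minid[k] <- v
      members[[k]] <- v
    } else if (length(nbc) == 1) {
      comp[v] <- nbc
      members[[nbc]] <- c(members[[nbc]], v)
    } else {
      # keep the catchment with the deepest minimum (stable tie-break)
      o <- order(comp_min[nbc], rank_of[comp_minid[nbc]])
      keep <- nbc[o[1]]
      for (cl in nbc[o[-1]]) {
        if (is_min[comp_minid[cl]]) {
          depth[comp_minid[cl]] <- Fv[v] - comp_min[cl]
        }
        comp[members[[cl]]] <- keep
        members[[keep]] <- c(members[[keep]], members[[cl]])
        members[[cl]] <- integer(0)
      }
      comp[v] <- keep
      members[[keep]] <- c(members[[keep]], v)
    }
  }

  ids <- which(is_min & depth > depth_threshold)
  ii <- ((ids - 1) %% n1) + 1
  jj <- ((ids - 1) %/% n1) + 1
  out <- tibble(i = ii, j = jj,
                !!fes$axes[[1]]$name := fes$x[ii],
                !!fes$axes[[2]]$name := fes$y[jj],
                free_energy = Fv[ids], depth = depth[ids])
  arrange(out, .data$free_energy)
}

# Minimal threshold T such that start and end are connected within
# {F <= T}: grow components over nodes in increasing F order.
.bottleneck_level <- function(F, start_id, end_id, per1, per2) {
  n1 <- nrow(F); n2 <- ncol(F)
  nb <- .neighbor_ids(n1, n2, per1, per2)
  Fv <- as.vector(F)
  ord <- order(Fv)
  comp <- integer(length(Fv))
  members <- list()
  for (v in ord) {
    nbc <- unique(comp[nb[[v]]])
    nbc <- nbc[nbc > 0]
    if (length(nbc) == 0) {
      k <- length(members) + 1L
      comp[v] <- k
      members[[k]] <- v
    } else {
      sizes <- lengths(members[nbc])
      keep <- nbc[which.max(sizes)]
      for (cl in setdiff(nbc, keep)) {
        comp[members[[cl]]] <- keep
        members[[keep]] <- c(members[[keep]], members[[cl]])
        members[[cl]] <- integer(0)
      }
      comp[v] <- keep
      members[[keep]] <- c(members[[keep]], v)
    }
    if (comp[start_id] > 0 && comp[start_id] == comp[end_id]) {
      return(Fv[v])
    }
  }
  abort("start and end are not connected on the grid")
}

# All undirected 8-connectivity edges restricted to admissible nodes.
.subgraph_edges <- function(ok, n1, n2, per1, per2) {
  idx <- matrix(seq_len(n1 * n2), n1, n2)
  elist <- vector("list", nrow(.moves))
  for (m in seq_len(nrow(.moves))) {
    ii <- seq_len(n1) + .moves[m, 1]
    jj <- seq_len(n2) + .moves[m, 2]
    if (per1) ii <- ((ii - 1) %% n1) + 1
    if (per2) jj <- ((jj - 1) %% n2) + 1
    vi <- which(ii >= 1 & ii <= n1)
    vj <- which(jj >= 1 & jj <= n2)
    if (length(vi) == 0 || length(vj) == 0) next
    src <- idx[vi, vj, drop = FALSE]
    dst <- idx[ii[vi], jj[vj], drop = FALSE]
    keep <- ok[src] & ok[dst] & src < dst
    elist[[m]] <- cbind(src[keep], dst[keep])
  }
  do.call(rbind, elist)
}

.node_id <- function(node, n1) {
  if (is.data.frame(node)) node <- c(node$i[1], node$j[1])
  node[1] + (node[2] - 1) * n1
}

#' Minimum free-energy path between two basins
#'
#' Returns the globally optimal grid path under the minimax criterion: the
#' path whose highest node is as low as possible.  Among minimax-optimal
#' paths, ties are broken by minimal total accumulated free energy, then by
#' fewest nodes.  Moves are 8-connected with periodic wrap on periodic
#' axes.
#'
#' @param fes an `fes_grid`.
#' @param start,end grid nodes as `c(i, j)` index pairs or single rows of
#'   [find_minima()] output.
#' @return an object of class `mfep_path`: a tibble of ordered nodes with
#'   columns `step`, `i`, `j`, the two CV coordinates, `free_energy`, and
#'   cumulative `arc_length` (CV units, periodic-aware).
#' @export
find_mfep <- function(fes, start, end) {
  F <- fes$values
  n1 <- nrow(F); n2 <- ncol(F)
  per1 <- fes$axes[[1]]$periodic; per2 <- fes$axes[[2]]$periodic
  s <- .node_id(start, n1)
  e <- .node_id(end, n1)
  if (s < 1 || s > n1 * n2 || e < 1 || e > n1 * n2) {
    abort("start/end node outside the grid")
  }

  if (s == e) {
    ids <- s
  } else {
    level <- .bottleneck_level(F, s, e, per1, per2)
    ok <- as.vector(F) <= level + 1e-12
    edges <- .subgraph_edges(ok, n1, n2, per1, per2)
    Fv <- as.vector(F)
    w <- (Fv[edges[, 1]] + Fv[edges[, 2]]) / 2 - min(Fv)
    # tiny per-edge cost breaks residual ties toward fewer nodes
    eps <- 1e-9 * max(1, max(abs(Fv)))
    g <- igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2), directed = FALSE)
    igraph::E(g)$weight <- w + eps
    sp <- igraph::shortest_paths(g, from = as.character(s),
                                 to = as.character(e), mode = "all",
                                 algorithm = "dijkstra")
    ids <- as.integer(igraph::as_ids(sp$vpath[[1]]))
    if (length(ids) == 0) abort("no admissible path found")
  }

  ii <- ((ids - 1) %% n1) + 1
  jj <- ((ids - 1) %/% n1) + 1
  xx <- fes$x[ii]; yy <- fes$y[jj]
  if (length(ids) > 1) {
    dx <- if (per1) min_image(xx[-1], xx[-length(xx)],
                              fes$axes[[1]]$max - fes$axes[[1]]$min)
          else diff(xx)
    dy <- if (per2) min_image(yy[-1], yy[-length(yy)],
                              fes$axes[[2]]$max - fes$axes[[2]]$min)
          else diff(yy)
    arc <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  } else {
    arc <- 0
  }
  out <- tibble(step = seq_along(ids), i = ii, j = jj,
                !!fes$axes[[1]]$name := xx,
                !!fes$axes[[2]]$name := yy,
                free_energy = F[cbind(ii, jj)], arc_length = arc)
  class(out) <- c("mfep_path", class(out))
  attr(out, "axes") <- fes$axes
  out
}

#' Activation and reaction free energy of a path
#'
#' \eqn{\Delta G^\ddagger} is the highest free energy along the path minus
#' the first node's; \eqn{\Delta G} is last minus first.  The transition
#' state is the first node attaining the maximum (a +/- 1 node window is
#' reported as its uncertainty).
#'
#' @param path an `mfep_path` (or any tibble with a `free_energy` column).
#' @return one-row tibble: `dg_activation`, `dg_reaction`, `ts_step`,
#'   `ts_step_lo`, `ts_step_hi` (energies kcal/mol).
#' @export
barrier_and_reaction_energy <- function(path) {
  if (nrow(path) == 0) abort("empty path")
  f <- path$free_energy
  ts <- which.max(f)
  tibble(
    dg_activation = max(f) - f[1],
    dg_reaction = f[length(f)] - f[1],
    ts_step = ts,
    ts_step_lo = max(1L, ts - 1L),
    ts_step_hi = min(length(f), ts + 1L)
  )
}

#' @method glance mfep_path
#' @export
glance.mfep_path <- function(x, ...) {
  dplyr::bind_cols(tibble(n_nodes = nrow(x),
                          path_length = max(x$arc_length)),
                   barrier_and_reaction_energy(x))
}

#' @method tidy mfep_path
#' @export
tidy.mfep_path <- function(x, ...) as_tibble(x)

#' @method autoplot mfep_path
#' @export
autoplot.mfep_path <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$arc_length, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "arc length (CV units)", y = "F (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Bin per-frame observables along a path
#'
#' Assigns each observation row to its nearest path node (Euclidean in CV
#' space, periodic-aware), then averages the observable columns within
#' consecutive arc-length bins of the stated width.  Bins containing no
#' data are flagged (`n = 0`, means `NA`), never interpolated.
#'
#' @param path an `mfep_path`.
#' @param observations tibble with the two CV columns (named as the path
#'   axes) plus one or more numeric observable columns.
#' @param bin_width arc-length bin width, CV units (> 0).
#' @return tibble with `bin`, `arc_mid`, `n`, and one mean column per
#'   observable.
#' @export
profile_along_path <- function(path, observations, bin_width = 0.2) {
  if (bin_width <= 0) abort("bin_width must be positive")
  axes <- attr(path, "axes")
  nx <- axes[[1]]$name; ny <- axes[[2]]$name
  check_columns(observations, c(nx, ny), "observable table")
  obs_cols <- setdiff(names(observations), c(nx, ny, "frame", "time"))

  px <- path[[nx]]; py <- path[[ny]]
  p1 <- axes[[1]]$max - axes[[1]]$min
  p2 <- axes[[2]]$max - axes[[2]]$min
  nearest <- vapply(seq_len(nrow(observations)), function(r) {
    dx <- if (axes[[1]]$periodic) min_image(observations[[nx]][r], px, p1)
          else observations[[nx]][r] - px
    dy <- if (axes[[2]]$periodic) min_image(observations[[ny]][r], py, p2)
          else observations[[ny]][r] - py
    which.min(dx^2 + dy^2)
  }, integer(1))
  arc <- path$arc_length[nearest]

  breaks <- seq(0, max(path$arc_length) + bin_width, by = bin_width)
  bin_id <- findInterval(arc, breaks, rightmost.closed = TRUE)
  all_bins <- seq_len(length(breaks) - 1)
  out <- tibble(
    bin = all_bins,
    arc_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    n = vapply(all_bins, function(b) sum(bin_id == b), integer(1))
  )
  for (cl in obs_cols) {
    out[[cl]] <- vapply(all_bins, function(b) {
      v <- observations[[cl]][bin_id == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  out
}
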