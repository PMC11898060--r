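# Well-tempered metadynamics free-energy surface reconstruction on 2D grids.

#' Describe one grid axis
#'
#' @param name axis (collective variable) name; must match a hills column.
#' @param min,max domain bounds.  A periodic axis must span exactly one
#'   period; its grid omits the duplicate endpoint.
#' @param n number of grid nodes (>= 2).
#' @param periodic is the axis periodic?
#' @return an object of class `grid_axis`.
#' @examples
#' grid_axis("phi", 0, 2 * pi, 144, periodic = TRUE)
#' @export
grid_axis <- function(name, min, max, n, periodic = FALSE) {
  if (max <= min) abort("grid axis needs max > min")
  if (n < 2) abort("grid axis needs at least 2 nodes")
  structure(list(name = name, min = min, max = max, n = as.integer(n),
                 periodic = isTRUE(periodic)),
            class = "grid_axis")
}

# Node coordinates of an axis.  Periodic axes use n equispaced nodes over
# one period without the duplicate endpoint; bounded axes include both ends.
axis_nodes <- function(ax) {
  if (ax$periodic) {
    ax$min + (ax$max - ax$min) * (seq_len(ax$n) - 1) / ax$n
  } else {
    seq(ax$min, ax$max, length.out = ax$n)
  }
}

axis_spacing <- function(ax) {
  if (ax$periodic) (ax$max - ax$min) / ax$n else (ax$max - ax$min) / (ax$n - 1)
}

# Signed difference x - center respecting periodicity.
axis_delta <- function(ax, x, center) {
  if (ax$periodic) min_image(x, center, ax$max - ax$min) else x - center
}

#' Default puckering-sphere grid axes
#'
#' phi periodic on `[0, 2*pi)` with 144 nodes, theta bounded on `[0, pi]`
#' with 72 nodes (radians), matching the 2D projection in which puckering
#' free-energy surfaces are conventionally drawn.
#'
#' @param n_phi,n_theta node counts.
#' @return list of two `grid_axis` objects.
#' @export
pucker_axes <- function(n_phi = 144, n_theta = 72) {
  list(grid_axis("phi", 0, 2 * pi, n_phi, periodic = TRUE),
       grid_axis("theta", 0, pi, n_theta, periodic = FALSE))
}

#' Reconstruct a well-tempered free-energy surface from hills
#'
#' Sums the deposited Gaussian bias on a 2D grid,
#' \eqn{V(s) = \sum_k w_k \exp(-\sum_i \Delta_i^2 / (2\sigma_{i,k}^2))},
#' with minimum-image differences on periodic axes, and converts bias to
#' free energy.  Under the `"tempered"` dialect the stored heights are the
#' as-deposited (already damped) heights and
#' \eqn{F(s) = -\gamma/(\gamma-1)\, V(s)}; under `"prescaled"` the heights
#' already include that factor and \eqn{F(s) = -V(s)}.  The surface is
#' shifted so its global minimum is zero.
#'
#' @param hills hills tibble ([read_hills()] / [sample_wt_metad()]).
#' @param axes list of two [grid_axis()] objects whose names match hills
#'   center columns.
#' @param dialect `"tempered"` (default) or `"prescaled"`.
#' @param gamma well-tempered bias factor; defaults to the hills `biasf`
#'   column.  Required (> 1) for the tempered dialect.
#' @return an object of class `fes_grid`: list with `axes`, node coordinate
#'   vectors `x`, `y`, and a `values` matrix (kcal/mol, min = 0).
#' @examples
#' fes <- reconstruct_fes(synthetic_hills_example(), pucker_axes(36, 18))
#' glance(fes)
#' @export
reconstruct_fes <- function(hills, axes, dialect = c("tempered", "prescaled"),
                            gamma = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(length(axes) == 2)
  nm <- c(axes[[1]]$name, axes[[2]]$name)
  check_columns(hills, c(nm, paste0("sigma_", nm), "height"), "hills table")

  if (is.null(gamma) && "biasf" %in% names(hills) && nrow(hills) > 0) {
    gamma <- hills$biasf[1]
  }
  if (dialect == "tempered") {
    if (nrow(hills) > 0 && (is.null(gamma) || gamma <= 1)) {
      abort("the tempered dialect needs a bias factor gamma > 1")
    }
    cfac <- if (is.null(gamma)) 1 else gamma / (gamma - 1)
  } else {
    cfac <- 1
  }

  x <- axis_nodes(axes[[1]])
  y <- axis_nodes(axes[[2]])
  V <- matrix(0, nrow = length(x), ncol = length(y))
  if (nrow(hills) > 0) {
    c1 <- hills[[nm[1]]]; c2 <- hills[[nm[2]]]
    s1 <- hills[[paste0("sigma_", nm[1])]]
    s2 <- hills[[paste0("sigma_", nm[2])]]
    w <- hills$height
    for (k in seq_len(nrow(hills))) {
      # separable Gaussian: one outer product per hill
      gx <- exp(-axis_delta(axes[[1]], x, c1[k])^2 / (2 * s1[k]^2))
      gy <- exp(-axis_delta(axes[[2]], y, c2[k])^2 / (2 * s2[k]^2))
      V <- V + w[k] * tcrossprod(gx, gy)
    }
  }
  F <- -cfac * V
  F <- F - min(F)
  structure(
    list(axes = axes, x = x, y = y, values = F,
         dialect = dialect, gamma = gamma, n_hills = nrow(hills)),
    class = "fes_grid"
  )
}

#' Build a free-energy grid from a value matrix
#'
#' Wraps an existing matrix of free energies (e.g. an analytic potential
#' evaluated on the grid nodes) as an `fes_grid`.
#'
#' @param values numeric matrix, rows along axis 1.
#' @param axes list of two [grid_axis()] objects.
#' @param shift shift so the minimum is zero (the class convention).
#' @return an `fes_grid`.
#' @export
as_fes_grid <- function(values, axes, shift = TRUE) {
  stopifnot(length(axes) == 2)
  x <- axis_nodes(axes[[1]]); y <- axis_nodes(axes[[2]])
  if (!all(dim(values) == c(length(x), length(y)))) {
    abort("values matrix does not match the axis grid")
  }
  if (!all(is.finite(values))) abort("free energies must be finite")
  if (shift) values <- values - min(values)
  structure(list(axes = axes, x = x, y = y, values = values,
                 dialect = NA_character_, gamma = NA_real_,
                 n_hills = NA_integer_),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("Free-energy surface: %d x %d grid (%s%s x %s%s)\n",
              length(x$x), length(x$y),
              x$axes[[1]]$name, if (x$axes[[1]]$periodic) " [periodic]" else "",
              x$axes[[2]]$name, if (x$axes[[2]]$periodic) " [periodic]" else ""))
  cat(sprintf("  range 0 - %.2f kcal/mol, reconstructed from %d hills\n",
              max(x$values), x$n_hills))
  invisible(x)
}

#' @rdname reconstruct_fes
#' @param x an `fes_grid`.
#' @param ... unused.
#' @method tidy fes_grid
#' @export
tidy.fes_grid <- function(x, ...) {
  out <- tidyr::expand_grid(i = seq_along(x$x), j = seq_along(x$y))
  out <- mutate(out,
                !!x$axes[[1]]$name := x$x[.data$i],
                !!x$axes[[2]]$name := x$y[.data$j],
                free_energy = x$values[cbind(out$i, out$j)])
  out
}

#' @rdname reconstruct_fes
#' @method glance fes_grid
#' @export
glance.fes_grid <- function(x, ...) {
  tibble(n_x = length(x$x), n_y = length(x$y), n_hills = x$n_hills,
         max_free_energy = max(x$values),
         converged_range_exceeded = max(x$values) > 14)
}

#' @method autoplot fes_grid
#' @export
autoplot.fes_grid <- function(object, ...) {
  df <- tidy(object)
  nx <- object$axes[[1]]$name
  ny <- object$axes[[2]]$name
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nx]], y = .data[[ny]],
                                   fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$free_energy),
                          colour = "white", linewidth = 0.2,
                          binwidth = 2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)", option = "turbo") +
    ggplot2::labs(x = nx, y = ny) +
    ggplot2::theme_minimal()
}

#' Write / read a gridded free-energy surface as text
#'
#' Plain-text format compatible with common sum-hills output: a header with
#' axis metadata, then one row per node (`x y free_energy`), y varying
#' fastest.
#'
#' @param fes an `fes_grid`.
#' @param path file path.
#' @return `path` (writer) or an `fes_grid` (reader).
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS %s %s free_energy",
                     fes$axes[[1]]$name, fes$axes[[2]]$name), con)
  for (ax in fes$axes) {
    writeLines(sprintf("#! SET min_%s %.17g", ax$name, ax$min), con)
    writeLines(sprintf("#! SET max_%s %.17g", ax$name, ax$max), con)
    writeLines(sprintf("#! SET nbins_%s %d", ax$name, ax$n), con)
    writeLines(sprintf("#! SET periodic_%s %s", ax$name,
                       if (ax$periodic) "true" else "false"), con)
  }
  grid <- tidy(fes)
  writeLines(sprintf("%.17g %.17g %.17g",
                     grid[[fes$axes[[1]]$name]],
                     grid[[fes$axes[[2]]$name]],
                     grid$free_energy), con)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  header <- grep("^#!", lines, value = TRUE)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "",
                         grep("FIELDS", header, value = TRUE)[1]), "\\s+")[[1]]
  nm <- fields[1:2]
  axes <- lapply(nm, function(cv) {
    grid_axis(
      cv,
      .hills_set_value(header, paste0("min_", cv)),
      .hills_set_value(header, paste0("max_", cv)),
      .hills_set_value(header, paste0("nbins_", cv)),
      periodic = grepl("true", grep(paste0("periodic_", cv), header,
                                    value = TRUE)[1])
    )
  })
  vals <- matrix(scan(text = lines[!grepl("^\\s*(#|$)", lines)], quiet = TRUE),
                 ncol = 3, byrow = TRUE)
  x <- axis_nodes(axes[[1]]); y <- axis_nodes(axes[[2]])
  F <- matrix(vals[, 3], nrow = length(x), ncol = length(y), byrow = TRUE)
  structure(list(axes = axes, x = x, y = y, values = F,
                 dialect = NA_character_, gamma = NA_real_, n_hills = NA_integer_),
            class = "fes_grid")
}

#' Boltzmann-aggregated free energy of a grid region
#'
#' \eqn{F_R = -kT \ln \sum_{s \in R} e^{-F(s)/kT}\,\Delta A}, with
#' \eqn{\Delta A} the uniform node area element of the grid.
#'
#' @param fes an `fes_grid`.
#' @param mask logical matrix of the same shape as `fes$values`.
#' @param kT thermal energy, kcal/mol (0.596 is 300 K).
#' @return free energy of the region, kcal/mol.
#' @export
region_free_energy <- function(fes, mask, kT = 0.596) {
  if (kT <= 0) abort("kT must be positive")
  if (!is.logical(mask) || !all(dim(mask) == dim(fes$values))) {
    abort("mask must be a logical matrix matching the grid shape")
  }
  if (!any(mask)) abort("region mask selects no grid nodes")
  dA <- axis_spacing(fes$axes[[1]]) * axis_spacing(fes$axes[[2]])
  -kT * log(sum(exp(-fes$values[mask] / kT)) * dA)
}

# Logical mask of reactive nodes for a puckering FES (axes in radians).
reactive_mask <- function(fes, spec = partition_spec()) {
  phi_deg <- rad2deg(fes$x)
  theta_deg <- rad2deg(fes$y)
  tb <- boundary_theta(spec, phi_deg)
  cmp <- if (spec$inclusive_side == "reactive") `<=` else `<`
  outer(seq_along(fes$x), seq_along(fes$y),
        function(i, j) cmp(theta_deg[j], tb[i]))
}

#' Reactive/nonreactive free-energy difference on a puckering FES
#'
#' Contrasts the free energy of the reactive region (north of the partition
#' boundary, toward the 4C1 chair) with the nonreactive region (south,
#' toward 1C4).  Negative values mean reactive conformations are favored.
#' The default `"boltzmann"` mode aggregates each region at temperature
#' `kT`; `"minimum"` mode takes the difference of the two region minima.
#'
#' @param fes `fes_grid` over the puckering angles, phi (axis 1, periodic,
#'   radians) by theta (axis 2, radians).
#' @param spec a [partition_spec()] (degrees).
#' @param kT thermal energy, kcal/mol.
#' @param mode `"boltzmann"` or `"minimum"`.
#' @return free-energy difference reactive - nonreactive, kcal/mol.
#' @export
delta_g_rnr <- function(fes, spec = partition_spec(), kT = 0.596,
                        mode = c("boltzmann", "minimum")) {
  mode <- match.arg(mode)
  mask <- reactive_mask(fes, spec)
  if (!any(mask) || all(mask)) {
    abort("partition leaves one region empty on this grid")
  }
  if (mode == "boltzmann") {
    region_free_energy(fes, mask, kT) - region_free_energy(fes, !mask, kT)
  } else {
    min(fes$values[mask]) - min(fes$values[!mask])
  }
}
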