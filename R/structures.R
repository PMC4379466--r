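#' Generate a ground-truth emitter structure
#'
#' Creates a set of fluorophore positions decorating a parametrized
#' structure inside a rectangular field of view, emulating the kinds of
#' labeled specimens seen in correlative SMLM/EM experiments: pairs of
#' parallel membranes, single membrane profiles, vesicle-like rings,
#' nuclear chromatin blobs, or a uniform field. Emitter counts are
#' Poisson-distributed around `density x measure` (areal density times area,
#' or linear density times contour length).
#'
#' @param kind One of `"membrane_pair"`, `"line"`, `"ring"`,
#'   `"nuclear_blobs"`, `"uniform"`.
#' @param params Named list of structure parameters. Common entries:
#'   `density_um2` (points per square micron; `uniform`, `nuclear_blobs`),
#'   `linear_density_um` (points per micron of contour; `line`,
#'   `membrane_pair`, `ring`), `spacing_nm` (membrane separation),
#'   `length_nm`, `angle_deg`, `radius_nm`, `n_blobs`, `blob_sigma_nm`.
#' @param field_of_view Length-2 numeric, FOV width and height in nm.
#' @param seed Integer seed; identical seeds give identical emitter sets.
#' @return An `emitter_set`: a tibble with columns `emitter_id`, `x_nm`,
#'   `y_nm`, with the structure kind, parameters and field of view attached
#'   as attributes (`structure_kind`, `structure_params`, `field_of_view`).
#' @export
#' @examples
#' em <- generate_structure("membrane_pair",
#'                          list(spacing_nm = 300, linear_density_um = 50),
#'                          field_of_view = c(4000, 4000), seed = 1)
#' nrow(em)
generate_structure <- function(kind, params = list(), field_of_view, seed) {
  kinds <- c("membrane_pair", "line", "ring", "nuclear_blobs", "uniform")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    stop_smlm(sprintf("generate_structure: unknown structure kind '%s' (expected one of %s)",
                      as.character(kind)[1], paste(kinds, collapse = ", ")))
  }
  stopifnot(length(field_of_view) == 2)
  if (any(field_of_view <= 0)) {
    stop_smlm("generate_structure: field_of_view must be positive in both dimensions")
  }
  w <- field_of_view[1]; h <- field_of_view[2]
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  neg <- vapply(params, function(v) is.numeric(v) && any(v < 0), logical(1))
  if (any(neg)) stop_smlm("generate_structure: structure parameters must be nonnegative")

  pts <- run_with_seed(seed, {
    switch(kind,
      uniform = {
        dens <- p("density_um2", 100)
        n <- rpois(1, dens * (w / 1000) * (h / 1000))
        cbind(runif(n, 0, w), runif(n, 0, h))
      },
      line = {
        len <- min(p("length_nm", 0.8 * min(w, h)), sqrt(w^2 + h^2))
        ang <- p("angle_deg", 0) * pi / 180
        dens <- p("linear_density_um", 50)
        n <- rpois(1, dens * len / 1000)
        t <- runif(n, -len / 2, len / 2)
        cbind(w / 2 + t * cos(ang), h / 2 + t * sin(ang))
      },
      membrane_pair = {
        spacing <- p("spacing_nm", 300)
        len <- min(p("length_nm", 0.8 * min(w, h)), sqrt(w^2 + h^2))
        ang <- p("angle_deg", 0) * pi / 180
        dens <- p("linear_density_um", 50)
        u <- c(cos(ang), sin(ang))          # along the membranes
        v <- c(-sin(ang), cos(ang))         # normal
        one <- function(off) {
          n <- rpois(1, dens * len / 1000)
          t <- runif(n, -len / 2, len / 2)
          cbind(w / 2 + t * u[1] + off * v[1], h / 2 + t * u[2] + off * v[2])
        }
        rbind(one(-spacing / 2), one(spacing / 2))
      },
      ring = {
        rad <- p("radius_nm", 0.25 * min(w, h))
        dens <- p("linear_density_um", 50)
        n <- rpois(1, dens * 2 * pi * rad / 1000)
        th <- runif(n, 0, 2 * pi)
        cbind(w / 2 + rad * cos(th), h / 2 + rad * sin(th))
      },
      nuclear_blobs = {
        dens <- p("density_um2", 500)
        nb <- p("n_blobs", 6)
        bs <- p("blob_sigma_nm", 200)
        n <- rpois(1, dens * (w / 1000) * (h / 1000))
        if (n == 0 || nb == 0) {
          matrix(numeric(0), 0, 2)
        } else {
          margin <- min(3 * bs, 0.25 * min(w, h))
          cx <- runif(nb, margin, w - margin)
          cy <- runif(nb, margin, h - margin)
          b <- sample.int(nb, n, replace = TRUE)
          cbind(cx[b] + rnorm(n, 0, bs), cy[b] + rnorm(n, 0, bs))
        }
      }
    )
  })
  if (nrow(pts) > 0) {
    pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), h)
  }
  out <- tibble(
    emitter_id = seq_len(nrow(pts)),
    x_nm = as.numeric(pts[, 1]),
    y_nm = as.numeric(pts[, 2])
  )
  attr(out, "structure_kind") <- kind
  attr(out, "structure_params") <- params
  attr(out, "field_of_view") <- field_of_view
  class(out) <- c("emitter_set", class(out))
  out
}

#' @export
print.emitter_set <- function(x, ...) {
  cat(sprintf("<emitter_set> %d emitters, kind '%s', FOV %g x %g nm\n",
              nrow(x), attr(x, "structure_kind"),
              attr(x, "field_of_view")[1], attr(x, "field_of_view")[2]))
  NextMethod()
}
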