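#' Create a PSM tissue
#'
#' The presomitic mesoderm is represented as a rectangular 3D lattice:
#' anterior-posterior (AP) layers x dorsoventral rows x mediolateral
#' columns. The posterior-most \code{gz_depth} layers form the growth
#' zone, where cells proliferate and transcribe \emph{Wnt3a}/\emph{Fgf8}.
#' The default geometry (4 x 4 cross-section, 15 initial layers = growth
#' zone only) simulates one half of the PSM at desk scale.
#'
#' @param n_rows,n_cols cross-section size (dorsoventral x mediolateral).
#' @param n_layers initial AP length in layers.
#' @param gz_depth growth-zone depth in layers (default 15).
#' @param state optional cells x 38 state matrix (cells ordered
#'   layer-major: layer 1 rows/cols first); defaults to all-zero.
#' @param time starting time (min).
#' @return an object of class \code{psm_tissue}.
#' @export
new_tissue <- function(n_rows = 4, n_cols = 4, n_layers = 15, gz_depth = 15,
                       state = NULL, time = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_layers >= 1, gz_depth >= 1)
  n <- n_rows * n_cols * n_layers
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols),
                      layer = seq_len(n_layers))
  if (is.null(state)) state <- new_state_matrix(n)
  stopifnot(nrow(state) == n, ncol(state) == n_psm_species())
  t <- structure(list(
    state = state,
    layer = grid$layer, row = grid$row, col = grid$col,
    id = seq_len(n), mother = rep(NA_integer_, n),
    birth_time = rep(time, n),
    epi_time = rep(NA_real_, n),
    n_rows = n_rows, n_cols = n_cols, n_layers = n_layers,
    gz_depth = gz_depth, next_id = n + 1L, time = time
  ), class = "psm_tissue")
  t
}

#' @export
print.psm_tissue <- function(x, ...) {
  cat("psm_tissue:", length(x$id), "cells |", x$n_layers, "AP layers x",
      x$n_rows, "rows x", x$n_cols, "cols | growth zone:",
      min(x$gz_depth, x$n_layers), "posterior layers | t =", x$time, "min |",
      sum(!is.na(x$epi_time)), "epithelialized\n")
  invisible(x)
}

#' Growth-zone membership
#'
#' The growth zone is always the posterior-most \code{gz_depth} AP layers.
#'
#' @param tissue a \code{psm_tissue}.
#' @return logical vector over cells.
#' @export
in_growth_zone <- function(tissue) {
  tissue$layer > tissue$n_layers - tissue$gz_depth
}

#' Face-adjacent neighbour topology in CSR form
#'
#' @param tissue a \code{psm_tissue}.
#' @return list with 0-based concatenated neighbour indices \code{idx},
#'   pointer vector \code{ptr} (length n+1), and the sparse averaging
#'   matrix \code{A} (row i holds 1/n_i on the neighbours of cell i).
#' @export
neighbor_topology <- function(tissue) {
  nl <- tissue$n_layers; nr <- tissue$n_rows; nc <- tissue$n_cols
  n <- length(tissue$id)
  pos <- array(0L, dim = c(nl, nr, nc))
  pos[cbind(tissue$layer, tissue$row, tissue$col)] <- seq_len(n)
  idx_list <- vector("list", n)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  lay <- tissue$layer; row <- tissue$row; col <- tissue$col
  nb <- matrix(0L, n, 6)
  cnt <- integer(n)
  for (k in 1:6) {
    l2 <- lay + off[k, 1]; r2 <- row + off[k, 2]; c2 <- col + off[k, 3]
    ok <- l2 >= 1 & l2 <= nl & r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- integer(n); j[ok] <- pos[cbind(l2[ok], r2[ok], c2[ok])]
    has <- ok & j > 0
    cnt <- cnt + has
    nb[, k] <- ifelse(has, j, 0L)
  }
  idx <- integer(sum(cnt))
  ptr <- integer(n + 1)
  p <- 0L
  for (i in seq_len(n)) {
    ptr[i] <- p
    js <- nb[i, ][nb[i, ] > 0L]
    if (length(js)) idx[(p + 1):(p + length(js))] <- js - 1L
    p <- p + length(js)
  }
  ptr[n + 1] <- p
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), cnt), j = idx + 1L, x = rep(1 / pmax(cnt, 1), cnt),
    dims = c(n, n))
  list(idx = idx, ptr = ptr, A = A)
}

#' Neighbour average of a species for one cell
#'
#' Arithmetic mean over face-adjacent lattice neighbours (up to 6;
#' boundary cells average over existing neighbours; 0 for an isolated
#' cell).
#'
#' @param tissue a \code{psm_tissue}.
#' @param cell_index cell index (1-based).
#' @param species one of \code{"dll1_pm"}, \code{"wnt3a_p"},
#'   \code{"fgf8_p"} (any state column is accepted).
#' @return mean concentration (a.u.).
#' @export
neighbor_average <- function(tissue, cell_index, species = "dll1_pm") {
  stopifnot(cell_index >= 1, cell_index <= length(tissue$id))
  topo <- neighbor_topology(tissue)
  a <- topo$ptr[cell_index] + 1L
  b <- topo$ptr[cell_index + 1L]
  if (b < a) return(0)
  js <- topo$idx[a:b] + 1L
  mean(tissue$state[js, species])
}

#' One round of growth-zone mitosis
#'
#' In every AP-aligned column a random growth-zone layer is chosen for
#' mitosis. The daughter is created at the mother's location as an exact
#' copy of her 38-variable state (daughters inherit the oscillation phase)
#' and pushes the mother and all more posterior cells of that column one
#' layer towards the posterior tip. The tissue gains one layer; growth-zone
#' membership is recomputed afterwards, so cells newly anterior to the
#' growth zone lose Wnt3a/Fgf8 transcription from the next evaluation.
#'
#' @param tissue a \code{psm_tissue}.
#' @param rng_layers optional integer vector (length rows x cols) of
#'   division layers, as depth 1..gz_depth from the growth-zone anterior
#'   edge; drawn uniformly from the RNG when NULL.
#' @return the grown \code{psm_tissue}.
#' @export
grow_step <- function(tissue, rng_layers = NULL) {
  nr <- tissue$n_rows; nc <- tissue$n_cols
  L <- tissue$n_layers
  gz0 <- L - min(tissue$gz_depth, L)  # layers > gz0 are in the growth zone
  ncolumns <- nr * nc
  if (is.null(rng_layers)) {
    rng_layers <- sample.int(L - gz0, ncolumns, replace = TRUE)
  }
  stopifnot(length(rng_layers) == ncolumns,
            all(rng_layers >= 1), all(rng_layers <= L - gz0))
  n <- length(tissue$id)
  cidx <- (tissue$col - 1L) * nr + tissue$row  # column key 1..ncolumns
  mother_layer <- gz0 + rng_layers             # per column
  # shift cells at/below the division site posteriorly
  shift <- tissue$layer >= mother_layer[cidx]
  new_layer <- tissue$layer + as.integer(shift)
  # locate mothers (cell at the division layer of each column)
  mother_of <- integer(ncolumns)
  sel <- which(tissue$layer == mother_layer[cidx])
  mother_of[cidx[sel]] <- sel
  if (any(mother_of == 0L)) stop("internal error: division site not found")
  # daughters: copies of the mothers, placed at the vacated layer
  m <- mother_of
  d_n <- length(m)
  tissue$state <- rbind(tissue$state, tissue$state[m, , drop = FALSE])
  tissue$layer <- c(new_layer, mother_layer)
  tissue$row <- c(tissue$row, tissue$row[m])
  tissue$col <- c(tissue$col, tissue$col[m])
  tissue$id <- c(tissue$id, seq(tissue$next_id, length.out = d_n))
  tissue$mother <- c(tissue$mother, tissue$id[m])
  tissue$birth_time <- c(tissue$birth_time, rep(tissue$time, d_n))
  tissue$epi_time <- c(tissue$epi_time, rep(NA_real_, d_n))
  tissue$next_id <- tissue$next_id + d_n
  tissue$n_layers <- L + 1L
  tissue
}

#' Flag epithelialized cells
#'
#' Cells whose EPHA4 protein is at or above the threshold are flagged
#' epithelialized, irreversibly; the flag records the crossing time and
#' does not alter the ODEs.
#'
#' @param tissue a \code{psm_tissue}.
#' @param params a \code{psm_params} (uses \code{epha4_threshold}).
#' @return updated tissue.
#' @export
apply_epithelialization <- function(tissue, params) {
  hit <- is.na(tissue$epi_time) &
    tissue$state[, "epha4_pc"] >= params$epha4_threshold
  tissue$epi_time[hit] <- tissue$time
  tissue
}

#' Tabular snapshot of a tissue
#'
#' @param x a \code{psm_tissue}.
#' @param ... unused.
#' @return data.frame with cell id, position, flags and all 38 variables.
#' @export
as.data.frame.psm_tissue <- function(x, ...) {
  cbind(
    data.frame(id = x$id, layer = x$layer, row = x$row, col = x$col,
               birth_time = x$birth_time,
               in_growth_zone = in_growth_zone(x),
               epithelialized = !is.na(x$epi_time),
               epi_time = x$epi_time,
               mother = x$mother),
    as.data.frame(x$state)
  )
}
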