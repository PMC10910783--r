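#' Construct a directed connectome
#'
#' A connectome couples a directed, weighted adjacency matrix with a region
#' metadata table. Entry `adjacency[i, j]` is the projection strength from
#' source region `i` to target region `j` (the anterograde direction).
#'
#' @param adjacency Square numeric matrix of non-negative projection
#'   strengths with a zero diagonal. Row/column order must match `regions`.
#' @param regions Data frame with one row per region and columns `acronym`
#'   (character), `hemisphere` (`"ipsi"` or `"contra"`), `size` (positive
#'   real, the source-region volume used for normalization), `x`, `y`, `z`
#'   (centroid coordinates in mm) and optionally `parent_acronym` and
#'   `n_daughters`.
#' @param seeds Optional character vector of seed-region acronyms
#'   (resolved in the ipsilateral hemisphere), carried as a convenience.
#'
#' @return An object of class `connectome`: a list with elements
#'   `adjacency` (matrix, dimnames set to `"<acronym>_<hemisphere>"`) and
#'   `regions` (tibble), plus the optional `seeds`.
#' @export
#' @examples
#' regs <- tibble::tibble(
#'   acronym = c("A", "B"), hemisphere = c("ipsi", "ipsi"),
#'   size = c(1, 1), x = c(0, 1), y = 0, z = 0
#' )
#' cn <- connectome(matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE), regs)
#' cn
connectome <- function(adjacency, regions, seeds = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be square.")
  }
  regions <- tibble::as_tibble(regions)
  required <- c("acronym", "hemisphere", "size", "x", "y", "z")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("`regions` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(regions) != nrow(adjacency)) {
    abort(sprintf(
      "`adjacency` is %d x %d but `regions` has %d rows.",
      nrow(adjacency), ncol(adjacency), nrow(regions)
    ))
  }
  if (!all(regions$hemisphere %in% c("ipsi", "contra"))) {
    abort("`regions$hemisphere` entries must be \"ipsi\" or \"contra\".")
  }
  labels <- region_label(regions$acronym, regions$hemisphere)
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    abort(paste0("Duplicate region (acronym, hemisphere) pairs: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(adjacency)) || any(adjacency < 0)) {
    abort("`adjacency` entries must be finite and >= 0.")
  }
  if (any(diag(adjacency) != 0)) {
    abort("`adjacency` must have a zero diagonal (no self-projections).")
  }
  if (!"parent_acronym" %in% names(regions)) regions$parent_acronym <- ""
  if (!"n_daughters" %in% names(regions)) regions$n_daughters <- 0L
  dimnames(adjacency) <- list(labels, labels)
  structure(
    list(adjacency = adjacency, regions = regions, seeds = seeds),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf(
    "<connectome> %d regions (%d ipsi, %d contra), %d directed edges\n",
    n, sum(x$regions$hemisphere == "ipsi"),
    sum(x$regions$hemisphere == "contra"),
    sum(x$adjacency > 0)
  ))
  if (!is.null(x$seeds)) {
    cat("  seeds:", paste(x$seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$adjacency)

#' Normalize projection strengths by source-region size
#'
#' Divides every outgoing edge weight by the size of its source region, so
#' that large regions do not dominate purely by volume:
#' `adjacency[i, j] / size[i]`.
#'
#' @param x A [connectome].
#' @return A `connectome` with rescaled adjacency; metadata unchanged.
#' @export
normalize_by_source_size <- function(x) {
  stopifnot(inherits(x, "connectome"))
  sizes <- x$regions$size
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    bad <- which(!is.finite(sizes) | sizes <= 0)
    abort(paste0(
      "All region sizes must be positive; offending region(s): ",
      paste(rownames(x$adjacency)[bad], collapse = ", ")
    ))
  }
  x$adjacency <- x$adjacency / sizes  # recycles down columns = by source row
  x
}

#' Build anterograde and retrograde out-degree graph Laplacians
#'
#' The anterograde Laplacian is `L_a = D_out - A` with `D_out` the diagonal
#' of row sums of the adjacency `A`; the retrograde Laplacian applies the
#' same construction to the transposed adjacency, `L_r = D'_out - t(A)`.
#' Both have zero row sums, non-positive off-diagonals and non-negative
#' diagonals, and generate the linear diffusion dynamics used by
#' [diffuse()].
#'
#' @param x A [connectome] (normally after [normalize_by_source_size()]).
#' @return An object of class `laplacian_pair`: list with matrices `L_a`
#'   and `L_r`.
#' @export
build_laplacians <- function(x) {
  stopifnot(inherits(x, "connectome"))
  A <- x$adjacency
  L_a <- diag(rowSums(A), nrow(A)) - A
  At <- t(A)
  L_r <- diag(rowSums(At), nrow(At)) - At
  dimnames(L_a) <- dimnames(L_r) <- dimnames(A)
  structure(list(L_a = L_a, L_r = L_r), class = "laplacian_pair")
}

#' @export
print.laplacian_pair <- function(x, ...) {
  cat(sprintf("<laplacian_pair> %d x %d out-degree Laplacians (L_a, L_r)\n",
              nrow(x$L_a), ncol(x$L_a)))
  invisible(x)
}

#' Build the binary seed indicator vector
#'
#' Resolves seed acronyms to ipsilateral regions and returns the indicator
#' vector `x0` with ones at the injection sites and zeros elsewhere.
#'
#' @param x A [connectome].
#' @param seed_acronyms Character vector of region acronyms; each must
#'   resolve to exactly one ipsilateral region. Defaults to the seeds
#'   stored in the connectome, if any.
#' @return An object of class `seed_vector`: list with `x0` (named 0/1
#'   vector) and `seed_acronyms`.
#' @export
make_seed_vector <- function(x, seed_acronyms = x$seeds) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(seed_acronyms) || length(seed_acronyms) == 0) {
    abort("`seed_acronyms` must contain at least one acronym.")
  }
  ipsi <- x$regions$hemisphere == "ipsi"
  idx <- vapply(seed_acronyms, function(a) {
    hits <- which(ipsi & x$regions$acronym == a)
    if (length(hits) == 0) return(NA_integer_)
    if (length(hits) > 1) return(-1L)
    hits
  }, integer(1))
  if (anyNA(idx) || any(idx == -1L, na.rm = TRUE)) {
    missing <- seed_acronyms[is.na(idx)]
    ambig <- seed_acronyms[!is.na(idx) & idx == -1L]
    msg <- c()
    if (length(missing)) {
      msg <- c(msg, paste0("unresolved: ", paste(missing, collapse = ", ")))
    }
    if (length(ambig)) {
      msg <- c(msg, paste0("ambiguous: ", paste(ambig, collapse = ", ")))
    }
    abort(paste0("Seed acronyms failed to resolve to unique ipsilateral ",
                 "regions (", paste(msg, collapse = "; "), ")."))
  }
  x0 <- setNames(numeric(nrow(x$adjacency)), rownames(x$adjacency))
  x0[idx] <- 1
  structure(list(x0 = x0, seed_acronyms = seed_acronyms,
                 index = unname(idx)),
            class = "seed_vector")
}

# Seed vector from raw region indices (used by the permutation null, whose
# random seed sets may span both hemispheres).
seed_vector_from_index <- function(x, index) {
  x0 <- setNames(numeric(nrow(x$adjacency)), rownames(x$adjacency))
  x0[index] <- 1
  structure(list(x0 = x0,
                 seed_acronyms = x$regions$acronym[index],
                 index = as.integer(index)),
            class = "seed_vector")
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param x A [connectome] with centroid columns `x`, `y`, `z` in mm.
#' @return Symmetric numeric matrix of distances in mm, zero diagonal,
#'   dimnames matching the adjacency.
#' @export
pairwise_centroid_distances <- function(x) {
  stopifnot(inherits(x, "connectome"))
  cen <- as.matrix(x$regions[, c("x", "y", "z")])
  if (any(!is.finite(cen))) {
    abort("All region centroids must be present and finite.")
  }
  d <- as.matrix(dist(cen))
  dimnames(d) <- dimnames(x$adjacency)
  d
}
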