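#' Electrode montages and the normalized graph adjacency
#'
#' The graph layer of the emotion-recognition network operates on a fixed
#' adjacency derived from electrode geometry: off-diagonal affinities are the
#' inverse Euclidean distance between channel positions, self-loops are added,
#' and the matrix is symmetrically degree-normalized. These functions build
#' and validate the montage and its normalized adjacency.
#'
#' @name montage
NULL

# (front-back step, lateral step) grid for the 62-channel 10/20-extended
# layout; 18 degrees per 10% step on an idealized spherical head.
.montage_grid <- function() {
  row <- function(ap, labels, lat) data.frame(name = labels, ap = ap, lat = lat,
                                              stringsAsFactors = FALSE)
  rbind(
    row(4L, c("FP1", "FPZ", "FP2"), c(-1, 0, 1)),
    row(3L, c("AF3", "AF4"), c(-1, 1)),
    row(2L, c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"),
        c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    row(1L, c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8"),
        c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    row(0L, c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"),
        c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    row(-1L, c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8"),
        c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    row(-2L, c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"),
        c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    row(-3L, c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8"),
        c(-4, -3, -2, 0, 2, 3, 4)),
    row(-4L, c("O1", "OZ", "O2"), c(-1, 0, 1)),
    row(-5L, c("CB1", "CB2"), c(-2, 2))
  )
}

#' Construct a channel montage
#'
#' A montage is an ordered set of channel labels with 3-D Cartesian positions
#' in millimeters (+x toward the nose, +y toward the left ear, +z toward the
#' vertex), the unit electrode position files conventionally use. With no
#' arguments the standard 62-channel 10/20-extended layout is returned, with
#' idealized positions on a 95 mm sphere generated from the electrode grid
#' by azimuthal-equidistant placement: a grid point (front-back, lateral)
#' steps from the vertex maps to a polar angle of 18 degrees per 10%
#' placement step along the azimuth of the grid direction. The millimeter
#' scale matters for the graph adjacency: the inverse-distance affinities
#' (order 0.01/mm) are then small against the unit self-loops of A + I, so
#' the normalized adjacency is diagonal-dominant and the graph layer mixes
#' each channel mostly with its near neighbours instead of averaging the
#' whole scalp.
#'
#' @param names character vector of unique channel labels.
#' @param coords numeric matrix, one row per channel, columns x/y/z.
#' @return An object of class `channel_montage`: list with `names` and
#'   `coords` (rownames set to the channel labels).
#' @examples
#' mon <- channel_montage()
#' nrow(mon$coords)  # 62
#' @export
channel_montage <- function(names = NULL, coords = NULL) {
  if (is.null(names) && is.null(coords)) {
    grid <- .montage_grid()
    step <- 18 * pi / 180
    radius <- 95                      # idealized scalp radius, mm
    coords <- radius * t(vapply(seq_len(nrow(grid)), function(i) {
      # azimuthal-equidistant placement: the flat (front-back, lateral) grid
      # point maps to polar angle 18 deg per 10% step from the vertex, with
      # the azimuth of the grid direction (nose = +x, left ear = +y)
      theta <- step * sqrt(grid$ap[i]^2 + grid$lat[i]^2)
      beta <- atan2(grid$lat[i], grid$ap[i])
      c(sin(theta) * cos(beta), -sin(theta) * sin(beta), cos(theta))
    }, numeric(3)))
    names <- grid$name
  }
  coords <- as.matrix(coords)
  if (!is.character(names) || anyDuplicated(names))
    stop("channel names must be a character vector without duplicates")
  if (nrow(coords) != length(names) || ncol(coords) != 3)
    stop("coords must be a ", length(names), " x 3 matrix")
  if (!all(is.finite(coords))) stop("coords must be finite")
  dimnames(coords) <- list(names, c("x", "y", "z"))
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("channels ", names[idx[1]], " and ", names[idx[2]],
         " share identical coordinates (zero distance)")
  }
  structure(list(names = names, coords = coords), class = "channel_montage")
}

#' @export
print.channel_montage <- function(x, ...) {
  cat("<channel_montage> ", length(x$names), " channels: ",
      paste(utils::head(x$names, 6), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Read a montage from a plain-text table
#'
#' Expects whitespace-separated columns `name x y z`, one row per channel
#' (header optional; detected from the first field).
#'
#' @param path file path.
#' @return A [channel_montage()].
#' @export
read_montage <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  header <- identical(tolower(first[1]), "name")
  tab <- if (header) utils::read.table(path, header = TRUE,
                                       stringsAsFactors = FALSE)
  else utils::read.table(path, header = FALSE,
                         col.names = c("name", "x", "y", "z"),
                         stringsAsFactors = FALSE)
  channel_montage(as.character(tab[[1]]), as.matrix(tab[, 2:4]))
}

#' Write a montage as a plain-text table
#'
#' @param montage a [channel_montage()].
#' @param path destination file.
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(name = montage$names, montage$coords, row.names = NULL)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Normalized graph adjacency of a montage
#'
#' Builds the affinity matrix A with zero diagonal and off-diagonal entries
#' 1/d(i, j) (inverse Euclidean distance between electrode positions), adds
#' self-loops (A-tilde = A + I), forms the diagonal degree matrix D-tilde of
#' A-tilde, and returns the symmetric normalization
#' S = D-tilde^{-1/2} (A + I) D-tilde^{-1/2} used by the graph layer.
#'
#' @param montage a [channel_montage()].
#' @return An object of class `normalized_adjacency`: list with `A`,
#'   `A_tilde`, `D_tilde` (diagonal vector), and `S`, all with channel
#'   dimnames.
#' @examples
#' S <- build_normalized_adjacency(channel_montage())$S
#' isSymmetric(S)
#' @export
build_normalized_adjacency <- function(montage) {
  stopifnot(inherits(montage, "channel_montage"))
  d <- as.matrix(stats::dist(montage$coords))
  A <- 1 / d
  diag(A) <- 0
  A_tilde <- A + diag(nrow(A))
  deg <- rowSums(A_tilde)
  inv_sqrt <- 1 / sqrt(deg)
  S <- A_tilde * outer(inv_sqrt, inv_sqrt)
  dimnames(S) <- dimnames(A) <- dimnames(A_tilde) <- list(montage$names, montage$names)
  if (!all(is.finite(S))) stop("normalized adjacency contains non-finite entries")
  structure(list(A = A, A_tilde = A_tilde, D_tilde = deg, S = S),
            class = "normalized_adjacency")
}
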