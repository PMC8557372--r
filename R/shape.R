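# Pentamer-lookup DNA shape encoding. Shape values are consumed from a table
# asset (pentamer -> value per shape feature); the package ships a synthetic
# table generated in code so all functionality is testable without licensed
# reference tables, and reads user-supplied published tables from TSV.

.SHAPE_CLASSES <- c(
  Shift = "inter", Slide = "inter", Rise = "inter",
  Tilt = "inter", Roll = "inter", HelT = "inter",
  Shear = "intra", Stretch = "intra", Stagger = "intra",
  Buckle = "intra", ProT = "intra", Opening = "intra",
  MGW = "intra", EP = "intra"
)

#' Names of the 14 DNA shape features
#' @return character vector: 6 inter-base-pair step features (shift, slide,
#'   rise, tilt, roll, helix twist) and 8 intra/groove features (shear,
#'   stretch, stagger, buckle, propeller twist, opening, minor groove width,
#'   electrostatic potential).
#' @export
shape_names <- function() names(.SHAPE_CLASSES)

# realistic per-shape location/scale (units: Angstrom or degrees)
.SHAPE_SCALES <- list(
  Shift = c(0, 0.25), Slide = c(-0.2, 0.4), Rise = c(3.32, 0.12),
  Tilt = c(0, 1.2), Roll = c(2.5, 2.5), HelT = c(34.5, 1.5),
  Shear = c(0, 0.15), Stretch = c(0, 0.08), Stagger = c(0, 0.2),
  Buckle = c(0, 4), ProT = c(-7, 3), Opening = c(1, 2),
  MGW = c(5.1, 0.6), EP = c(-5, 1.5)
)

#' Synthetic pentamer DNA shape table
#'
#' A deterministic, code-generated stand-in for published pentamer shape
#' tables: for each shape a set of 16 dinucleotide step parameters is drawn
#' (fixed internal seed) and each pentamer's value is derived from the step
#' parameters of its central steps plus a small pentamer-specific term. This
#' reproduces the dominant real-data property that base-stacking shape
#' features are largely dinucleotide-dependent, at realistic locations and
#' scales per shape. It is synthetic: values do not reproduce any published
#' table numerically. The generating step parameters are attached as
#' `attr(, "steps")` so simulations can plant shape-correlated signal.
#'
#' @return a `tn5_shape_table`: per shape, class ("inter"/"intra") and named
#'   value vectors over all 1024 pentamers (`v1`, and `v2` for inter shapes:
#'   the two central step values).
#' @export
synthetic_shape_table <- function() {
  pent <- all_kmers(5L)
  # dinucleotide indices of the two central steps (bases 2-3 and 3-4)
  d2 <- paste0(substr(pent, 2, 2), substr(pent, 3, 3))
  d3 <- paste0(substr(pent, 3, 3), substr(pent, 4, 4))
  dinucs <- all_kmers(2L)
  shapes <- list()
  steps_out <- list()
  with_seed(774421L, {
    for (i in seq_along(.SHAPE_CLASSES)) {
      nm <- names(.SHAPE_CLASSES)[i]
      cls <- .SHAPE_CLASSES[[nm]]
      sc <- .SHAPE_SCALES[[nm]]
      step <- stats::setNames(rnorm(16, sc[1], sc[2]), dinucs)
      jit1 <- rnorm(1024, 0, 0.15 * sc[2])
      jit2 <- rnorm(1024, 0, 0.15 * sc[2])
      if (cls == "inter") {
        v1 <- stats::setNames(step[d2] + jit1, pent)
        v2 <- stats::setNames(step[d3] + jit2, pent)
      } else {
        v1 <- stats::setNames((step[d2] + step[d3]) / 2 + jit1, pent)
        v2 <- NULL
      }
      shapes[[nm]] <- list(name = nm, class = cls, v1 = v1, v2 = v2)
      steps_out[[nm]] <- step
    }
  })
  structure(list(shapes = shapes, source = "synthetic"),
            class = "tn5_shape_table", steps = steps_out)
}

#' @export
print.tn5_shape_table <- function(x, ...) {
  cat("tn5_shape_table:", length(x$shapes), "shapes,",
      length(x$shapes[[1]]$v1), "pentamers, source:", x$source, "\n")
  invisible(x)
}

#' Read a pentamer shape table from TSV
#'
#' Schema: columns `pentamer`, `shape`, `class`, `value1`, `value2` (value2
#' empty/NA for intra shapes). All 1024 pentamers must be present per shape.
#'
#' @param path TSV file.
#' @return a `tn5_shape_table`.
#' @export
read_shape_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("pentamer", "shape", "class", "value1") %in% names(df)))
  shapes <- list()
  for (nm in unique(df$shape)) {
    d <- df[df$shape == nm, , drop = FALSE]
    stopifnot(nrow(d) == 1024, !anyDuplicated(d$pentamer))
    cls <- d$class[1]
    v1 <- stats::setNames(d$value1, d$pentamer)[all_kmers(5L)]
    v2 <- NULL
    if (cls == "inter") {
      stopifnot("value2" %in% names(d), !any(is.na(d$value2)))
      v2 <- stats::setNames(d$value2, d$pentamer)[all_kmers(5L)]
    }
    shapes[[nm]] <- list(name = nm, class = cls, v1 = v1, v2 = v2)
  }
  structure(list(shapes = shapes, source = path), class = "tn5_shape_table")
}

#' Write a shape table as TSV
#' @param table a `tn5_shape_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shape_table <- function(table, path) {
  rows <- lapply(table$shapes, function(s) {
    data.frame(pentamer = names(s$v1), shape = s$name, class = s$class,
               value1 = as.numeric(s$v1),
               value2 = if (is.null(s$v2)) NA_real_ else as.numeric(s$v2),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Shuffle a shape table
#'
#' Permutes values across pentamers (per shape; `v1`/`v2` move together) with
#' a seeded permutation, exactly preserving the value multiset. Shuffled
#' tables are the negative control that breaks the sequence-shape
#' relationship while keeping the value distribution.
#'
#' @param table a `tn5_shape_table`.
#' @param seed integer seed; distinct seeds give independent replicates.
#' @return a shuffled `tn5_shape_table`.
#' @export
shuffle_shape_table <- function(table, seed) {
  with_seed(child_seed(seed, "shuffle"), {
    shapes <- lapply(table$shapes, function(s) {
      perm <- sample.int(length(s$v1))
      v1 <- stats::setNames(as.numeric(s$v1)[perm], names(s$v1))
      v2 <- if (is.null(s$v2)) NULL
            else stats::setNames(as.numeric(s$v2)[perm], names(s$v2))
      list(name = s$name, class = s$class, v1 = v1, v2 = v2)
    })
    structure(list(shapes = shapes,
                   source = paste0(table$source, ":shuffled:", seed)),
              class = "tn5_shape_table")
  })
}

#' Encode sequence windows as DNA shape vectors
#'
#' Sliding-pentamer lookup: each position with a full pentamer context
#' (positions 3..L-2, 5'->3') receives one value per shape. Intra shapes use
#' the pentamer value directly; inter (step) shapes average the two
#' central-step values of the pentamer, giving equal vector lengths (L-4)
#' across shapes. Window edges without a pentamer are dropped, not imputed.
#'
#' @param seqs character vector of equal-length N-free windows (length >= 5).
#' @param table a `tn5_shape_table`.
#' @param shapes shape names to encode (default all 14).
#' @return numeric matrix, one row per window; columns named
#'   `<shape>_<position>` with 1-based window positions 3..L-2.
#' @export
encode_shape <- function(seqs, table, shapes = shape_names()) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1, L >= 5, !any(grepl("[^ACGT]", seqs)))
  n_cent <- L - 4L
  n <- length(seqs)
  # pentamer matrix: n x n_cent
  pent <- matrix("", n, n_cent)
  for (c0 in seq_len(n_cent)) {
    pent[, c0] <- substring(seqs, c0, c0 + 4L)
  }
  out <- matrix(NA_real_, n, length(shapes) * n_cent)
  cn <- character(ncol(out))
  for (i in seq_along(shapes)) {
    s <- table$shapes[[shapes[i]]]
    if (is.null(s)) stop("shape not in table: ", shapes[i])
    vals <- if (s$class == "inter") (s$v1[pent] + s$v2[pent]) / 2
            else s$v1[pent]
    cols <- ((i - 1L) * n_cent + 1L):(i * n_cent)
    out[, cols] <- matrix(vals, n, n_cent)
    cn[cols] <- paste0(shapes[i], "_", seq_len(n_cent) + 2L)
  }
  colnames(out) <- cn
  out
}
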