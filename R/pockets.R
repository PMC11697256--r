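#' Extract cysteine thiol (SG) coordinates from a structure file
#'
#' Reads a PDB or mmCIF file (first model when several are present) and
#' returns the gamma-sulfur coordinates of every cysteine residue — the
#' atoms whose proximity to Fpocket alpha spheres defines pocket
#' membership. CYS residues lacking an SG atom are skipped with a warning.
#'
#' @param path Structure file; format taken from the extension
#'   (`.pdb` vs `.cif`/`.mmcif`) unless `format` is given.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return Tibble: `chain`, `residue_index` (author numbering from the
#'   file), `x`, `y`, `z` (Angstrom), `source_model`.
#' @export
extract_thiol_coords <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "cif"
    } else {
      "pdb"
    }
  }
  struct <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  }
  at <- struct$atom
  cys <- at[at$resid == "CYS", , drop = FALSE]
  sg <- cys[cys$elety == "SG", , drop = FALSE]
  no_sg <- unique(cys$resno[!cys$resno %in% sg$resno])
  if (length(no_sg) > 0) {
    warning(sprintf(
      "CYS residue(s) without SG atom skipped: %s",
      paste(no_sg, collapse = ", ")
    ))
  }
  tibble(
    chain = as.character(sg$chain),
    residue_index = as.integer(sg$resno),
    x = sg$x, y = sg$y, z = sg$z,
    source_model = basename(path)
  )
}

#' Parse Fpocket alpha-sphere output (pockets PQR dialect)
#'
#' Reads the `*_pockets.pqr` file written by Fpocket: one ATOM/HETATM record
#' per alpha sphere, with the pocket number in the residue-sequence field
#' and the sphere radius in the last column. Non-record lines (headers,
#' comments, TER/END) are ignored; a truncated record line is an error
#' naming the line number.
#'
#' @param path PQR file path. An empty file yields an empty tibble (a
#'   protein without detected pockets).
#' @return Tibble: `pocket_id`, `x`, `y`, `z`, `radius` (Angstrom).
#' @export
parse_alpha_spheres <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_rec <- grepl("^(ATOM|HETATM)", lines)
  empty <- tibble(
    pocket_id = integer(), x = numeric(), y = numeric(), z = numeric(),
    radius = numeric()
  )
  if (!any(is_rec)) {
    return(empty)
  }
  rec_lines <- which(is_rec)
  parse_line <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 9) {
      stop_format(sprintf("truncated alpha-sphere record at line %d", i))
    }
    # numeric tail: x y z charge radius; pocket id precedes the tail
    tail5 <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
    pocket <- suppressWarnings(as.integer(tok[length(tok) - 5]))
    if (any(is.na(tail5)) || is.na(pocket)) {
      stop_format(sprintf("malformed alpha-sphere record at line %d", i))
    }
    c(pocket, tail5[1], tail5[2], tail5[3], tail5[5])
  }
  m <- vapply(rec_lines, parse_line, numeric(5))
  tibble(
    pocket_id = as.integer(m[1, ]),
    x = m[2, ], y = m[3, ], z = m[4, ], radius = m[5, ]
  )
}

#' Classify cysteines as pocket-proximal
#'
#' A cysteine is "in a pocket" when its thiol (SG) atom lies within `cutoff`
#' (default 1.5 Angstrom) of the closest alpha sphere. Under the default
#' `"center"` convention the distance is to the sphere center; under
#' `"surface"` the sphere radius is subtracted first
#' (`distance - radius <= cutoff`). The minimum distance and nearest pocket
#' are always reported, and the convention used is recorded in the output.
#'
#' @param thiols Tibble from [extract_thiol_coords()].
#' @param spheres Tibble from [parse_alpha_spheres()]. With no spheres, all
#'   calls are `FALSE` with infinite distance.
#' @param cutoff Proximity cutoff in Angstrom (default 1.5).
#' @param convention `"center"` (default) or `"surface"`.
#' @return Tibble: thiol identities, `in_pocket`, `min_distance`,
#'   `nearest_pocket_id`, `convention`.
#' @export
classify_pocket_proximity <- function(thiols, spheres, cutoff = 1.5,
                                      convention = c("center", "surface")) {
  convention <- match.arg(convention)
  n_t <- nrow(thiols)
  if (nrow(spheres) == 0) {
    return(mutate(
      thiols,
      in_pocket = FALSE, min_distance = Inf,
      nearest_pocket_id = NA_integer_, convention = convention
    ))
  }
  tm <- as.matrix(thiols[, c("x", "y", "z")])
  sm <- as.matrix(spheres[, c("x", "y", "z")])
  d2 <- outer(rowSums(tm^2), rowSums(sm^2), "+") - 2 * tm %*% t(sm)
  d <- sqrt(pmax(d2, 0))
  if (convention == "surface") {
    d <- sweep(d, 2, spheres$radius)
  }
  nearest <- apply(d, 1, which.min)
  min_d <- d[cbind(seq_len(n_t), nearest)]
  mutate(
    thiols,
    in_pocket = min_d <= cutoff,
    min_distance = min_d,
    nearest_pocket_id = spheres$pocket_id[nearest],
    convention = convention
  )
}
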