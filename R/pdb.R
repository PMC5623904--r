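# Minimal fixed-width PDB reader/writer. Written in-package: no installed
# R package parses PDB coordinate files, and the contract here (multi-model
# support, insertion codes, line-numbered errors) is small and specific.

.parse_atom_lines <- function(lines, line_no) {
  pad <- function(l) formatC(l, width = 80, flag = "-")
  lines <- vapply(lines, pad, character(1), USE.NAMES = FALSE)
  fx <- function(from, to) trimws(substring(lines, from, to))
  num <- function(from, to, what) {
    raw <- fx(from, to)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | raw == "")
    if (length(bad)) {
      stop(sprintf("malformed %s field in PDB line %d: '%s'", what,
                   line_no[bad[1L]], trimws(lines[bad[1L]])), call. = FALSE)
    }
    v
  }
  data.frame(
    record = fx(1, 6),
    serial = suppressWarnings(as.integer(fx(7, 11))),
    name = fx(13, 16),
    altloc = fx(17, 17),
    resname = fx(18, 20),
    chain = fx(22, 22),
    resseq = as.integer(num(23, 26, "residue number")),
    icode = fx(27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    bfactor = suppressWarnings(as.numeric(fx(61, 66))),
    element = fx(77, 78)
  )
}

#' Read a (multi-model) PDB file
#'
#' Parses ATOM and HETATM records, preserving residue numbering, chain
#' identifiers and insertion codes. `MODEL`/`ENDMDL` blocks yield ordered
#' models; files without MODEL records yield a single model. Malformed
#' coordinate fields raise an error naming the offending line number.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_structure`: a list with `models` (a list
#'   of data frames with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`) and `path`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  model_id <- integer(length(lines))
  cur <- 1L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r == "MODEL") {
      if (seen_model) cur <- cur + 1L
      seen_model <- TRUE
    }
    model_id[i] <- cur
  }
  idx <- which(is_atom)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  models <- lapply(split(idx, model_id[idx]), function(ii) {
    .parse_atom_lines(lines[ii], ii)
  })
  names(models) <- NULL
  structure(list(models = models, path = path), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  m1 <- x$models[[1L]]
  cat("PDB structure:", length(x$models), "model(s),", nrow(m1),
      "atoms,", length(unique(paste(m1$chain, m1$resseq, m1$icode))),
      "residues\n")
  invisible(x)
}

.format_atom_lines <- function(df) {
  name4 <- vapply(df$name, function(n) {
    if (nchar(n) >= 4L) substr(n, 1, 4) else sprintf(" %-3s", n)
  }, character(1), USE.NAMES = FALSE)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          df$record, df$serial %% 100000L, name4,
          ifelse(is.na(df$altloc), "", df$altloc), df$resname, df$chain,
          df$resseq %% 10000L, ifelse(is.na(df$icode), "", df$icode),
          df$x, df$y, df$z,
          ifelse(is.na(df$occupancy), 1, df$occupancy),
          ifelse(is.na(df$bfactor), 0, df$bfactor),
          df$element)
}

#' Write a structure (or atom table) to PDB format
#'
#' Multiple models are wrapped in `MODEL`/`ENDMDL` records. Beyond plain
#' structures this is used to export coarse-grained receptor models (one
#' pseudo-atom per bead, bead charge stored in the B-factor column) and
#' synthetic trajectories (one model per frame).
#'
#' @param x A `pdb_structure`, a single atom data frame, or a list of atom
#'   data frames (one per model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  models <- if (inherits(x, "pdb_structure")) {
    x$models
  } else if (is.data.frame(x)) {
    list(x)
  } else {
    x
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(.format_atom_lines(models[[i]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
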