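#' Named binding-parameter presets for all measured complexes
#'
#' Returns one entry per complex characterised by fluorescence titration:
#' the wild-type Nter-NPM1 domain against the Fbw7gamma*, CENP-W* and Tat*
#' NoLS peptides, the twelve alanine mutants of the acidic surface residues
#' against Fbw7gamma*, and the triple/quadruple/quintuple mutants against
#' CENP-W* and Tat*. Each entry carries the measured dissociation constant
#' (`kd`, uM) with its reported standard deviation (`kd_sd`), the peptide
#' sequence and its parent-protein numbering offset, and default optical
#' constants `b = 1`, `c = 0`, `k = 0.001` per uM (the raw fluorescence
#' scales were never published; these defaults make the linear drift visible
#' but small).
#'
#' Two non-binding control peptides (`unrelated_long`, `unrelated_short`)
#' are included with `kd = NA` ("no interaction").
#'
#' @return A named list; each element has fields `params`
#'   ([binding_params()] or `NULL` for non-binders), `kd_sd`, `peptide`,
#'   `sequence`, `first_residue` (parent numbering of the first peptide
#'   residue), `protein` (receptor variant label) and `table` (1, 2 or 3,
#'   the source summary table).
#' @examples
#' binding_presets()[["wt_fbw7g"]]$params$kd   # 3.2 uM
#' @export
binding_presets <- function() {
  seqs <- list(
    fbw7g = list(sequence = "LPFCRRRMKRKLDH", first_residue = 43L),
    cenpw = list(sequence = "KRKAPRGFLKRVFKRKK", first_residue = 14L),
    tat = list(sequence = "AGRKKRRQRRRPPQ", first_residue = 47L),
    unrelated_long = list(sequence = "DDEAQTLAKFVLSQK", first_residue = 1L),
    unrelated_short = list(sequence = "VLSQK", first_residue = 1L)
  )
  entry <- function(kd, kd_sd, peptide, protein, table) {
    s <- seqs[[peptide]]
    list(params = if (is.na(kd)) NULL else binding_params(kd = kd),
         kd_sd = kd_sd, peptide = peptide, sequence = s$sequence,
         first_residue = s$first_residue, protein = protein, table = table)
  }
  wt <- "Nter-NPM1"
  list(
    # Table 1: wild-type domain vs NoLS peptides (+ controls)
    wt_fbw7g = entry(3.2, 0.6, "fbw7g", wt, 1L),
    wt_cenpw = entry(6.2, 0.9, "cenpw", wt, 1L),
    wt_tat = entry(2.4, 0.5, "tat", wt, 1L),
    unrelated_long = entry(NA_real_, NA_real_, "unrelated_long", wt, 1L),
    unrelated_short = entry(NA_real_, NA_real_, "unrelated_short", wt, 1L),
    # Table 2: acidic-surface mutants vs Fbw7gamma*
    d36a_fbw7g = entry(10.8, 2.6, "fbw7g", "D36A", 2L),
    e37a_fbw7g = entry(12.5, 1.4, "fbw7g", "E37A", 2L),
    e39a_fbw7g = entry(6.2, 1.5, "fbw7g", "E39A", 2L),
    e93a_fbw7g = entry(5.0, 1.6, "fbw7g", "E93A", 2L),
    e121a_fbw7g = entry(13.3, 3.8, "fbw7g", "E121A", 2L),
    d36a_e39a_fbw7g = entry(13.5, 2.0, "fbw7g", "D36A-E39A", 2L),
    d36a_e93a_fbw7g = entry(8.4, 1.5, "fbw7g", "D36A-E93A", 2L),
    e39a_e93a_fbw7g = entry(7.6, 1.9, "fbw7g", "E39A-E93A", 2L),
    triple_fbw7g = entry(22.0, 3.0, "fbw7g", "D36A-E39A-E93A", 2L),
    quad_e37a_fbw7g = entry(151.5, 20.5, "fbw7g", "D36A-E37A-E39A-E93A", 2L),
    quad_e121a_fbw7g = entry(224.3, 35.9, "fbw7g", "D36A-E39A-E93A-E121A", 2L),
    quintuple_fbw7g = entry(653.7, 46.9, "fbw7g",
                            "D36A-E37A-E39A-E93A-E121A", 2L),
    # Table 3: selected mutants vs CENP-W* and Tat*
    triple_cenpw = entry(18.4, 2.6, "cenpw", "D36A-E39A-E93A", 3L),
    quad_e37a_cenpw = entry(71.4, 9.1, "cenpw", "D36A-E37A-E39A-E93A", 3L),
    quad_e121a_cenpw = entry(82.8, 5.6, "cenpw", "D36A-E39A-E93A-E121A", 3L),
    quintuple_cenpw = entry(734.0, 158.0, "cenpw",
                            "D36A-E37A-E39A-E93A-E121A", 3L),
    triple_tat = entry(11.1, 2.1, "tat", "D36A-E39A-E93A", 3L),
    quad_e37a_tat = entry(57.4, 7.0, "tat", "D36A-E37A-E39A-E93A", 3L),
    quad_e121a_tat = entry(63.8, 5.0, "tat", "D36A-E39A-E93A-E121A", 3L),
    quintuple_tat = entry(642.6, 70.8, "tat",
                          "D36A-E37A-E39A-E93A-E121A", 3L)
  )
}

#' Titration experiment design
#'
#' @param a_values Ordered varied-species (protein) concentrations, uM;
#'   non-negative and strictly increasing.
#' @param replicates Number of replicate curves (default 3, matching the
#'   triplicate experimental protocol).
#' @param noise_cv Multiplicative Gaussian coefficient of variation applied
#'   to the model fluorescence (default 0.02).
#' @param seed RNG seed for reproducible noise (integer or `NULL`).
#' @return An object of class `titration_design`.
#' @examples
#' titration_design(seq(0, 200, length.out = 25), noise_cv = 0)
#' @export
titration_design <- function(a_values, replicates = 3L, noise_cv = 0.02,
                             seed = NULL) {
  stopifnot(is.numeric(a_values), length(a_values) >= 2L)
  if (any(a_values < 0)) stop("protein concentrations must be non-negative")
  if (any(diff(a_values) <= 0)) {
    stop("protein concentrations must be strictly increasing")
  }
  stopifnot(replicates >= 1L, noise_cv >= 0)
  structure(list(a_values = as.numeric(a_values),
                 replicates = as.integer(replicates),
                 noise_cv = noise_cv, seed = seed),
            class = "titration_design")
}

#' Simulate a fluorescence titration
#'
#' Generates replicate titration curves under the quadratic binding model:
#' `F_ij = quadratic_model(a_i; params) * (1 + eps_ij)` with
#' `eps_ij ~ Normal(0, noise_cv)`. With `noise_cv = 0` the curve lies
#' exactly on the model. The RNG state is restored on exit when a seed is
#' given, so generation is reproducible and side-effect free.
#'
#' @param params A [binding_params()] object.
#' @param design A [titration_design()] object.
#' @return A `titration_curve`: a data frame with columns `replicate`,
#'   `a_uM`, `fluorescence`, plus attribute `n_fixed` (peptide
#'   concentration, uM).
#' @examples
#' wt <- binding_presets()[["wt_fbw7g"]]$params
#' make_titration(wt, titration_design(seq(0, 200, 10), noise_cv = 0))
#' @export
make_titration <- function(params, design) {
  stopifnot(inherits(params, "binding_params"),
            inherits(design, "titration_design"))
  a <- design$a_values
  f0 <- quadratic_model(a, params)
  na <- length(a)
  nr <- design$replicates
  noise <- if (design$noise_cv > 0) {
    with_seed(design$seed, rnorm(na * nr, 0, design$noise_cv))
  } else {
    numeric(na * nr)
  }
  out <- data.frame(
    replicate = rep(seq_len(nr), each = na),
    a_uM = rep(a, nr),
    fluorescence = rep(f0, nr) * (1 + noise)
  )
  titration_curve(out, n_fixed = params$n)
}

#' Construct a titration curve container
#'
#' @param data A data frame with columns `replicate`, `a_uM`,
#'   `fluorescence` (a missing `replicate` column is filled with 1).
#' @param n_fixed Fixed peptide concentration (uM), default 5.
#' @return A data frame of class `titration_curve`.
#' @export
titration_curve <- function(data, n_fixed = 5) {
  stopifnot(is.data.frame(data))
  if (is.null(data$replicate)) data$replicate <- 1L
  stopifnot(all(c("a_uM", "fluorescence") %in% names(data)))
  if (any(data$a_uM < 0)) stop("protein concentrations must be non-negative")
  stopifnot(n_fixed > 0)
  structure(data, n_fixed = n_fixed,
            class = c("titration_curve", "data.frame"))
}

#' Write / read a titration curve as CSV
#'
#' Plain CSV with columns `replicate`, `a_uM`, `fluorescence`; the fixed
#' peptide concentration is stored in a `# n_fixed_uM:` header comment.
#'
#' @param curve A `titration_curve`.
#' @param path Output/input file path.
#' @return `write_titration()` returns `path` invisibly; `read_titration()`
#'   returns a `titration_curve`.
#' @export
write_titration <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_fixed_uM: %.10g", attr(curve, "n_fixed")), con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  first <- readLines(path, n = 1L)
  n_fixed <- 5
  if (grepl("^# n_fixed_uM:", first)) {
    n_fixed <- as.numeric(sub("^# n_fixed_uM:", "", first))
  }
  df <- read.csv(path, comment.char = "#")
  titration_curve(df, n_fixed = n_fixed)
}

# Run code with a temporary RNG seed, restoring the prior state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
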