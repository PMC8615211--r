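#' Default configuration for MDAR signal scanning and classification
#'
#' All feature-detection thresholds used by the motif scanners and the
#' classifier live in one list so that every cutoff is user-replaceable.
#' Defaults follow classic single-pass transmembrane detection settings
#' (Kyte-Doolittle window 19, mean >= 1.6) and the targeting-signal
#' conventions of the plant peroxisome literature.
#'
#' @param ... named overrides for any default entry.
#'
#' @return A named list with entries:
#' \describe{
#'   \item{pts1_list}{accepted PTS1-like tripeptides (beyond canonical SKL).}
#'   \item{pts1_pattern_enabled}{logical; admit the loose tripeptide pattern
#'     \code{[ASC][KRNS][LIVMF]} as a third tier (off by default).}
#'   \item{tm_window}{odd window size for hydropathy averaging (residues).}
#'   \item{tm_threshold}{mean Kyte-Doolittle hydropathy calling a window
#'     transmembrane-like.}
#'   \item{cterm_margin}{a TM span counts as C-terminal when it ends within
#'     this many residues of the sequence end.}
#'   \item{tail_window}{how far past the TM the basic cluster may start.}
#'   \item{min_basic}{minimum K/R residues in a 6-residue window to call a
#'     basic cluster.}
#'   \item{min_extension}{minimum N-terminal extension length (residues)
#'     before the organellar heuristic is consulted.}
#'   \item{organellar_threshold}{composition score above which an extension
#'     is called organellar.}
#'   \item{organellar_head_len}{how many extension residues the composition
#'     score is computed over.}
#'   \item{typical_length_range}{inclusive residue-length range outside of
#'     which a sequence is flagged atypical.}
#'   \item{catalytic_positions}{named list mapping residue labels to
#'     \code{list(pos, residue)} in ungapped reference coordinates.}
#' }
#' @export
#' @examples
#' cfg <- mdar_config(tm_threshold = 1.8)
#' cfg$tm_threshold
mdar_config <- function(...) {
  cfg <- list(
    pts1_list = c("AKI", "AKV", "ASL", "SNL", "SKV", "SKI", "SKF", "SRI",
                  "CKM", "CKI"),
    pts1_pattern_enabled = FALSE,
    tm_window = 19L,
    tm_threshold = 1.6,
    cterm_margin = 40L,
    tail_window = 10L,
    min_basic = 4L,
    min_extension = 30L,
    organellar_threshold = 0.05,
    organellar_head_len = 50L,
    typical_length_range = c(400L, 552L),
    catalytic_positions = list(
      R320 = list(pos = 320L, residue = "R"),
      Y349 = list(pos = 349L, residue = "Y")
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown config entries: ", paste(bad, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' Read a key-value configuration file
#'
#' Parses a plain-text file of `key = value` lines (lines starting with `#`
#' are comments) into overrides for [mdar_config()]. Comma-separated values
#' become vectors; numeric-looking values are converted; `true`/`false`
#' become logicals. Catalytic positions use the compact form
#' `catalytic_positions = R320:320:R,Y349:349:Y`.
#'
#' @param path path to the configuration file.
#' @return The full configuration list (defaults plus overrides).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (key == "catalytic_positions") {
      entries <- lapply(parts, function(p) {
        f <- strsplit(p, ":", fixed = TRUE)[[1]]
        if (length(f) != 3) stop("malformed catalytic position: ", p)
        list(pos = as.integer(f[2]), residue = f[3])
      })
      names(entries) <- vapply(parts, function(p) {
        strsplit(p, ":", fixed = TRUE)[[1]][1]
      }, character(1))
      overrides[[key]] <- entries
      next
    }
    suppressWarnings(num <- as.numeric(parts))
    if (!anyNA(num)) {
      parts <- num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      parts <- tolower(parts) == "true"
    }
    overrides[[key]] <- parts
  }
  do.call(mdar_config, overrides)
}
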