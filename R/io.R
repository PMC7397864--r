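#' @name screen_io
#' @title Reading and writing screen tables
#'
#' @description All interchange files are plain text: tab-separated tables
#' with a header row and optional `#`-prefixed metadata lines, GMT files
#' for gene sets, and JSON for truth/summary objects.
NULL

#' Write a data frame as TSV with metadata header lines
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character vector written as `# key: value` lines.
#' @export
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0) {
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame (metadata lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

matrix_to_df <- function(m, id_col) {
  df <- data.frame(rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  df
}

df_to_matrix <- function(df, id_col) {
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a synthetic screen to a directory of plain-text files
#'
#' Emits `confluence.tsv`, `kd_efficiency.tsv`, `expression.tsv`,
#' `sample_sheet.tsv`, `site_counts.tsv`, `gene_sets.gmt`,
#' `morphology.tsv`, and `truth.json`. Every TSV carries `#` metadata
#' lines recording the seed and a configuration digest so runs can be
#' traced.
#'
#' @param screen A [simulate_screen()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- c(seed = as.character(screen$config$seed),
            config_hash = config_hash(screen$config))
  write_tsv(screen$confluence, file.path(dir, "confluence.tsv"), meta)
  write_tsv(screen$kd, file.path(dir, "kd_efficiency.tsv"), meta)
  write_tsv(matrix_to_df(screen$expression, "gene"),
            file.path(dir, "expression.tsv"), meta)
  write_tsv(screen$sample_sheet, file.path(dir, "sample_sheet.tsv"), meta)
  write_tsv(matrix_to_df(screen$site_counts, "gene"),
            file.path(dir, "site_counts.tsv"), meta)
  write_gmt(screen$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(screen$morphology, file.path(dir, "morphology.tsv"), meta)
  truth <- screen$truth
  truth$motif_activities <- if (is.null(truth$motif_activities)) NULL else
    matrix_to_df(truth$motif_activities, "motif")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a screen directory written by [write_screen()]
#'
#' @param dir Directory containing the screen tables.
#' @return A list with the same analysis inputs as a
#'   [simulate_screen()] object (`truth` is included when present).
#' @export
read_screen <- function(dir) {
  need <- c("confluence.tsv", "kd_efficiency.tsv", "expression.tsv",
            "sample_sheet.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing screen input file: ", file.path(dir, f), call. = FALSE)
    }
  }
  out <- list(
    confluence = read_tsv(file.path(dir, "confluence.tsv")),
    kd = read_tsv(file.path(dir, "kd_efficiency.tsv")),
    expression = df_to_matrix(read_tsv(file.path(dir, "expression.tsv")),
                              "gene"),
    sample_sheet = read_tsv(file.path(dir, "sample_sheet.tsv"))
  )
  out$sample_sheet$is_control <- as.logical(out$sample_sheet$is_control)
  opt <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  out$site_counts <- opt("site_counts.tsv",
                         function(p) df_to_matrix(read_tsv(p), "gene"))
  out$gene_sets <- opt("gene_sets.gmt", read_gmt)
  out$morphology <- opt("morphology.tsv", read_tsv)
  out$truth <- opt("truth.json",
                   function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  class(out) <- "synthetic_screen"
  out
}

## Small polynomial content digest used to stamp output files with the
## configuration they came from (no cryptographic intent).
config_hash <- function(config) {
  cfg <- unclass(config)
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 65599 + b) %% 2147483647
  sprintf("%08x", h)
}
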