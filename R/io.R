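flux_cols <- c("jar_id", "soil", "amendment", "replicate", "time_h",
               "flux_ugC_g_h", "delta13C_permil")
jar_cols <- c("jar_id", "soil", "amendment", "replicate", "soil_mass_g",
              "harvest_day")
amendment_levels <- c("soil", "OM", "PyOM")

check_amendment <- function(x, where) {
  bad <- which(!x %in% amendment_levels)
  if (length(bad) > 0L) {
    stop(where, " row ", bad[1], ": amendment \"", x[bad[1]],
         "\" not in {", paste(amendment_levels, collapse = ", "), "}")
  }
}

#' Read (and write) the gas flux CSV
#'
#' Schema: `jar_id, soil, amendment, replicate, time_h, flux_ugC_g_h,
#' delta13C_permil`. Comment lines starting with `#` carry provenance and
#' are skipped. Malformed rows (negative flux, negative time, unknown
#' amendment) are rejected with row context.
#'
#' @param path File path.
#' @return List with `measurements` (jar_id, time_h, flux, delta) and
#'   `jars` (jar_id, soil, amendment, replicate; mass and harvest day are
#'   `NA` -- they live in the jar metadata TSV).
#' @export
read_flux_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L) stop("empty flux file: ", path)
  missing <- setdiff(flux_cols, names(df))
  if (length(missing) > 0L) {
    stop("flux file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  check_amendment(df$amendment, basename(path))
  if (any(df$flux_ugC_g_h < 0)) {
    stop(basename(path), " row ", which(df$flux_ugC_g_h < 0)[1],
         ": negative flux")
  }
  if (any(df$time_h < 0)) {
    stop(basename(path), " row ", which(df$time_h < 0)[1],
         ": negative time_h")
  }
  list(measurements = tibble::tibble(jar_id = df$jar_id,
                                     time_h = df$time_h,
                                     flux = df$flux_ugC_g_h,
                                     delta = df$delta13C_permil),
       jars = dplyr::distinct(tibble::tibble(
         jar_id = df$jar_id, soil = df$soil, amendment = df$amendment,
         replicate = df$replicate)))
}

#' @rdname read_flux_csv
#' @param measurements,jars As produced by [simulate_incubation()].
#' @param header Optional provenance lines written as `#` comments.
#' @export
write_flux_csv <- function(measurements, jars, path, header = NULL) {
  df <- dplyr::inner_join(measurements, jars, by = "jar_id")
  out <- tibble::tibble(jar_id = df$jar_id, soil = df$soil,
                        amendment = df$amendment,
                        replicate = df$replicate, time_h = df$time_h,
                        flux_ugC_g_h = df$flux,
                        delta13C_permil = df$delta)
  write_with_header(out, path, header, delim = ",")
  invisible(path)
}

#' Read (and write) the jar metadata TSV
#'
#' Schema: `jar_id, soil, amendment, replicate, soil_mass_g,
#' harvest_day`.
#'
#' @param path File path.
#' @return Tibble of jar metadata.
#' @export
read_jar_metadata <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L) stop("empty jar metadata file: ", path)
  missing <- setdiff(jar_cols, names(df))
  if (length(missing) > 0L) {
    stop("jar file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  check_amendment(df$amendment, basename(path))
  if (anyDuplicated(df$jar_id)) stop("duplicate jar_id in ", path)
  if (any(df$replicate < 1)) stop("replicate indices must be >= 1")
  tibble::as_tibble(df[, jar_cols])
}

#' @rdname read_jar_metadata
#' @param jars Jar metadata tibble.
#' @param header Optional provenance comment lines.
#' @export
write_jar_metadata <- function(jars, path, header = NULL) {
  write_with_header(jars[, jar_cols], path, header, delim = "\t")
  invisible(path)
}

#' Read an OTU count table with sample metadata
#'
#' Accepts a TSV (rows = OTUs, first column `otu_id`, one column per
#' sample, integer counts) or a BIOM-format JSON file (parsed with the
#' biomformat package; extension `.biom` or `.json`). Sample metadata is
#' a TSV with columns `sample_id, soil, amendment, day, replicate`.
#' Samples lacking metadata are rejected by name.
#'
#' @param path Count table path (TSV or BIOM JSON).
#' @param metadata_path Sample metadata TSV path.
#' @param marker Marker label stored on the table.
#' @return An [amplicon_table()].
#' @export
read_otu_table <- function(path, metadata_path, marker = "16S") {
  if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))  # samples x OTUs
  } else {
    df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    if (nrow(df) == 0L) stop("empty OTU table: ", path)
    if (names(df)[1] != "otu_id") {
      stop("OTU TSV must have `otu_id` as its first column")
    }
    counts <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(counts) <- df$otu_id
  }
  if (any(counts != round(counts))) {
    stop("non-integer counts in ", path)
  }
  meta <- readr::read_tsv(metadata_path, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  check_amendment(meta$amendment, basename(metadata_path))
  amplicon_table(counts, meta, marker = marker)
}

#' @rdname read_otu_table
#' @param table An [amplicon_table()].
#' @param header Optional provenance comment lines.
#' @export
write_otu_table <- function(table, path, metadata_path, header = NULL) {
  stopifnot(inherits(table, "amplicon_table"))
  df <- tibble::as_tibble(t(table$counts), rownames = "otu_id")
  write_with_header(df, path, header, delim = "\t")
  write_with_header(table$metadata, metadata_path, header, delim = "\t")
  invisible(c(path, metadata_path))
}

write_with_header <- function(df, path, header = NULL, delim = ",") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  readr::write_delim(df, con, delim = delim)
}

provenance_header <- function(seed, config = list()) {
  c(sprintf("seed=%s", seed),
    sprintf("config_hash=%s", rlang::hash(config)),
    sprintf("soilpriming_version=%s",
            as.character(utils::packageVersion("soilpriming"))))
}
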