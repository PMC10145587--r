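#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Minimal fixed-width reader for ATOM/HETATM/MODEL/ENDMDL records —
#' enough for the coordinate fixtures this toolkit works with. All models
#' must share the same atom records.
#'
#' @param path PDB file
#' @return a [structure_ensemble()]
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of[] <- 1
  model_of[model_of == 0] <- 1
  atom_lines <- lines[is_atom]
  atom_model <- model_of[is_atom]
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path)
  models <- split(atom_lines, atom_model)
  n0 <- length(models[[1]])
  for (m in seq_along(models)) {
    if (length(models[[m]]) != n0) {
      stop(sprintf("inconsistent atom count in model %s: %d vs %d",
                   names(models)[m], length(models[[m]]), n0))
    }
  }
  parse_fields <- function(ln) {
    name <- trimws(substr(ln, 13, 16))
    elem <- trimws(substr(ln, 77, 78))
    # element fallback from the atom name: first alphabetic character
    fallback <- sub("^[0-9']*", "", name)
    fallback <- toupper(substr(fallback, 1, 1))
    data.frame(
      record = trimws(substr(ln, 1, 6)),
      name = name,
      resname = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      resid = as.integer(substr(ln, 23, 26)),
      element = ifelse(elem == "", fallback, elem))
  }
  atoms <- parse_fields(models[[1]])
  coords <- array(NA_real_, dim = c(n0, 3, length(models)))
  for (m in seq_along(models)) {
    ln <- models[[m]]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (anyNA(xyz)) stop("unparseable coordinates in model ", names(models)[m])
    coords[, , m] <- xyz
  }
  structure_ensemble(atoms, coords)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' @param ensemble a [structure_ensemble()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  a <- ensemble$atoms
  fmt_name <- ifelse(nchar(a$name) >= 4, sprintf("%-4s", a$name),
                     sprintf(" %-3s", a$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ensemble, f)
    writeLines(sprintf(
      "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, seq_len(nrow(a)), fmt_name, a$resname, a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XVG-dialect two-column series
#'
#' Lines starting with `#` or `@` are comments (retained as metadata);
#' data lines hold at least two whitespace-separated numeric columns:
#' index/time and value.
#'
#' @param path input file
#' @return a [sample_series()]; comment lines in `meta$comments`
#' @export
read_xvg_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^[#@]", lines) | !nzchar(trimws(lines))
  data_lines <- which(!is_comment)
  if (!length(data_lines)) stop("no data lines (empty series) in ", path)
  parts <- strsplit(trimws(lines[data_lines]), "[[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad)) {
    stop(sprintf("line %d of %s: fewer than 2 columns", data_lines[bad[1]], path))
  }
  tv <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1:2])), numeric(2))
  if (anyNA(tv)) {
    bad <- data_lines[which(colSums(is.na(tv)) > 0)[1]]
    stop(sprintf("line %d of %s: non-numeric data", bad, path))
  }
  seed <- NA_integer_
  seed_line <- grep("^[#@].*seed[ =:]+-?[0-9]+", lines, value = TRUE)
  if (length(seed_line)) {
    seed <- as.integer(sub(".*seed[ =:]+(-?[0-9]+).*", "\\1", seed_line[1]))
  }
  sample_series(tv[2, ], time = tv[1, ], seed = seed,
                meta = list(comments = lines[grepl("^[#@]", lines)]))
}

#' Write a sample series in XVG dialect
#'
#' @param series a [sample_series()]
#' @param path output file
#' @param comments extra comment lines (written with a leading `#`)
#' @return `path`, invisibly
#' @export
write_xvg_series <- function(series, path, comments = character(0)) {
  stopifnot(inherits(series, "sample_series"))
  hdr <- c(paste0("# ", comments),
           if (!is.na(series$seed)) sprintf("# seed = %d", series$seed),
           "@ xaxis label \"sample\"", "@ yaxis label \"value\"")
  body <- sprintf("%.17g %.17g", series$time, series$value)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an umbrella-window manifest
#'
#' Tab- or whitespace-separated table with a header line and columns
#' `file`, `center`, `k` (kJ/mol/nm^2). File paths are resolved relative
#' to the manifest's directory.
#'
#' @param path manifest file
#' @return data frame with absolute `file` paths
#' @export
read_window_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("file", "center", "k")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  abs <- file.path(base, tab$file)
  abs[file.exists(tab$file)] <- tab$file[file.exists(tab$file)]
  tab$file <- abs
  tab
}

#' Load umbrella windows from a manifest
#'
#' @param manifest path to a manifest or the data frame from
#'   [read_window_manifest()]
#' @return list of [umbrella_window()]
#' @export
load_umbrella_windows <- function(manifest) {
  if (is.character(manifest)) manifest <- read_window_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    if (!file.exists(manifest$file[i])) {
      stop("window sample file not found: ", manifest$file[i])
    }
    umbrella_window(manifest$center[i], manifest$k[i],
                    read_xvg_series(manifest$file[i]))
  })
}

#' Read a sectioned key = value run configuration
#'
#' Flat text dialect: `[section]` headers, `key = value` lines, `#`
#' comments. Values are split on whitespace and converted to numeric
#' where possible.
#'
#' @param path config file
#' @return named list of sections, each a named list of values
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "main"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      nums <- suppressWarnings(as.numeric(parts))
      if (!anyNA(nums)) parts <- nums
      if (length(parts) == 0) parts <- ""
      cfg[[section]][[key]] <- parts
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  cfg
}

#' Write a PMF profile as TSV
#' @param profile a `pmf_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pmf_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  utils::write.table(
    data.frame(r = profile$bin_centers, w = profile$w, stderr = profile$stderr),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PMF profile from TSV (columns r, w, stderr)
#' @param path input file
#' @param temperature temperature in K
#' @return a `pmf_profile`
#' @export
read_pmf_tsv <- function(path, temperature = 300) {
  tab <- utils::read.table(path, header = TRUE)
  pmf_profile(tab$r, tab$w, tab$stderr, temperature = temperature)
}
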