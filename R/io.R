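# titration CSV layout: '#'-prefixed comment/metadata header, then a header
# row and comma-separated numeric columns. Column names carry explicit units.
.col_map <- c(pH = "pH",
              mobility = "mobility_m2_per_V_s",
              sigma = "sigma_C_per_m2",
              sd_sigma = "sd_sigma_C_per_m2",
              n_replicates = "n_replicates")

.fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a titration dataset to CSV
#'
#' Writes the standard titration table: `#`-prefixed metadata header lines
#' (electrolyte, membrane and free-form provenance), a header row, and one
#' comma-separated row per pH with unit-qualified column names
#' (`pH`, `mobility_m2_per_V_s`, `sigma_C_per_m2`, `sd_sigma_C_per_m2`,
#' `n_replicates`). Numbers are printed with 17 significant digits so the
#' write/read round trip is value-exact.
#'
#' @param dataset A [titration_dataset()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @seealso [read_titration()]
#' @export
write_titration <- function(dataset, path) {
  stopifnot(inherits(dataset, "pcion_titration"))
  el <- dataset$electrolyte
  mem <- dataset$membrane
  hdr <- c(
    "# pcion titration v1",
    sprintf("# electrolyte.cation: %s", el$cation),
    sprintf("# electrolyte.c_salt_mol_per_m3: %s", .fmt(el$c_salt)),
    sprintf("# electrolyte.temperature_K: %s", .fmt(el$temperature)),
    sprintf("# electrolyte.Kw_mol2_per_m6: %s", .fmt(el$Kw)),
    sprintf("# electrolyte.epsilon_r: %s", .fmt(el$epsilon_r)),
    sprintf("# electrolyte.eta_Pa_s: %s", .fmt(el$eta)),
    sprintf("# electrolyte.ionic_strength_mol_per_m3: %s",
            .fmt(el$ionic_strength)),
    sprintf("# membrane.area_per_lipid_m2: %s", .fmt(mem$area_per_lipid))
  )
  meta <- dataset$metadata
  verbatim <- meta$comments
  meta$comments <- NULL
  for (k in names(meta)) {
    hdr <- c(hdr, sprintf("# meta.%s: %s", k,
                          if (is.numeric(meta[[k]])) .fmt(meta[[k]])
                          else as.character(meta[[k]])))
  }
  hdr <- c(hdr, verbatim)

  pts <- dataset$points
  cols <- intersect(names(.col_map), names(pts))
  body <- do.call(paste, c(lapply(cols, function(cn) .fmt(pts[[cn]])),
                           sep = ","))
  writeLines(c(hdr, paste(.col_map[cols], collapse = ","), body), path)
  invisible(path)
}

#' Read a titration dataset from CSV
#'
#' Parses the format written by [write_titration()]. Files must carry a `pH`
#' column and at least one of `mobility_m2_per_V_s` / `sigma_C_per_m2`;
#' violations, duplicate columns, and non-numeric cells raise parse errors
#' naming the offending column or line. Metadata comment lines are restored;
#' unrecognized comment lines are preserved verbatim in
#' `metadata$comments`. If the header does not embed the electrolyte and
#' membrane descriptions, they must be supplied as arguments.
#'
#' @param path File to read.
#' @param electrolyte,membrane Optional [electrolyte_spec()] /
#'   [membrane_spec()] overriding (or substituting for) the file header.
#' @return A [titration_dataset()].
#' @export
read_titration <- function(path, electrolyte = NULL, membrane = NULL) {
  if (!file.exists(path)) {
    pc_abort(sprintf("file not found: %s", path), "pcion_error_invalid_input")
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines), "#")
  is_blank <- trimws(lines) == ""
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) < 2L) {
    pc_abort("no data rows found", "pcion_error_parse")
  }

  # metadata from '# key: value' comments; anything else kept verbatim
  meta <- list()
  comments <- character()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3 && m[2] != "pcion titration v1") {
      meta[[m[2]]] <- m[3]
    } else if (!grepl("pcion titration", ln)) {
      comments <- c(comments, ln)
    }
  }

  header <- strsplit(lines[data_idx[1]], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (anyDuplicated(header)) {
    pc_abort(sprintf("duplicate column '%s' in header (line %d)",
                     header[duplicated(header)][1], data_idx[1]),
             "pcion_error_parse")
  }
  if (!"pH" %in% header) {
    pc_abort(sprintf("missing required column 'pH' (line %d)", data_idx[1]),
             "pcion_error_parse")
  }
  if (!any(c("mobility_m2_per_V_s", "sigma_C_per_m2") %in% header)) {
    pc_abort(sprintf(
      "missing measurement column: need 'mobility_m2_per_V_s' or 'sigma_C_per_m2' (line %d)",
      data_idx[1]), "pcion_error_parse")
  }

  rows <- lines[data_idx[-1]]
  cells <- strsplit(rows, ",", fixed = TRUE)
  bad_len <- which(lengths(cells) != length(header))
  if (length(bad_len)) {
    pc_abort(sprintf("line %d has %d fields, expected %d",
                     data_idx[-1][bad_len[1]],
                     lengths(cells)[bad_len[1]], length(header)),
             "pcion_error_parse")
  }
  mat <- do.call(rbind, cells)
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad <- which(is.na(num) & !(trimws(mat) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    pc_abort(sprintf("non-numeric value '%s' in column '%s' (line %d)",
                     mat[bad[1, 1], bad[1, 2]], header[bad[1, 2]],
                     data_idx[-1][bad[1, 1]]),
             "pcion_error_parse")
  }
  tab <- as.data.frame(num)
  names(tab) <- header
  inv <- setNames(names(.col_map), .col_map)
  names(tab) <- ifelse(names(tab) %in% names(inv), inv[names(tab)], names(tab))

  mnum <- function(key) as.numeric(meta[[key]])
  if (is.null(electrolyte)) {
    if (!is.null(meta[["electrolyte.c_salt_mol_per_m3"]])) {
      electrolyte <- electrolyte_spec(
        cation = meta[["electrolyte.cation"]],
        c_salt = mnum("electrolyte.c_salt_mol_per_m3"),
        temperature = mnum("electrolyte.temperature_K"),
        Kw = mnum("electrolyte.Kw_mol2_per_m6"),
        epsilon_r = mnum("electrolyte.epsilon_r"),
        eta = mnum("electrolyte.eta_Pa_s"),
        ionic_strength = mnum("electrolyte.ionic_strength_mol_per_m3"))
    } else {
      pc_abort("file has no electrolyte header; pass `electrolyte`",
               "pcion_error_invalid_input")
    }
  }
  if (is.null(membrane)) {
    if (!is.null(meta[["electrolyte.c_salt_mol_per_m3"]]) &&
        !is.null(meta[["membrane.area_per_lipid_m2"]])) {
      membrane <- membrane_spec(mnum("membrane.area_per_lipid_m2"))
    } else {
      pc_abort("file has no membrane header; pass `membrane`",
               "pcion_error_invalid_input")
    }
  }

  user_meta <- meta[startsWith(names(meta), "meta.")]
  names(user_meta) <- sub("^meta\\.", "", names(user_meta))
  user_meta <- lapply(user_meta, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  if (length(comments)) user_meta$comments <- comments

  titration_dataset(tab, electrolyte, membrane, metadata = user_meta)
}

#' Read and write association-constant files
#'
#' Plain key--value text: one `K_xx = value` line per constant, `#` comments,
#' and an optional `scale` key. `scale = SI` (default) means all values are
#' in m\eqn{^3}/mol; `scale = table` means the conventional reporting-table
#' column units (`K_AMe` in 1e-1, `K_AH` in 1e2, `K_BOH` in 1, `K_BCl` in
#' 1e-2 m\eqn{^3}/mol), which are converted to SI on read. Files always
#' state their scale so unit errors cannot pass silently.
#'
#' @param path File path.
#' @return `read_constants()`: an [association_constants()] object (SI).
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) {
    pc_abort(sprintf("file not found: %s", path), "pcion_error_invalid_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & trimws(lines) != ""]
  kv <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i],
                    regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)\\s*$",
                            lines[i]))[[1]]
    if (length(m) != 3) {
      pc_abort(sprintf("cannot parse constants line: '%s'", lines[i]),
               "pcion_error_parse")
    }
    kv[[m[2]]] <- m[3]
  }
  need <- c("K_AH", "K_AMe", "K_BOH", "K_BCl")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    pc_abort(sprintf("constants file missing key(s): %s",
                     paste(miss, collapse = ", ")),
             "pcion_error_parse")
  }
  vals <- vapply(kv[need], function(v) suppressWarnings(as.numeric(v)),
                 numeric(1))
  if (any(is.na(vals))) {
    pc_abort("non-numeric association constant value", "pcion_error_parse")
  }
  scale <- if (!is.null(kv$scale)) kv$scale else "SI"
  if (identical(scale, "table")) {
    constants_from_table(vals)
  } else if (identical(scale, "SI")) {
    association_constants(vals[["K_AH"]], vals[["K_AMe"]],
                          vals[["K_BOH"]], vals[["K_BCl"]])
  } else {
    pc_abort(sprintf("unknown scale '%s' (use 'SI' or 'table')", scale),
             "pcion_error_parse")
  }
}

#' @rdname read_constants
#' @param constants An [association_constants()] object (SI m\eqn{^3}/mol).
#' @export
write_constants <- function(constants, path) {
  stopifnot(inherits(constants, "pcion_constants"))
  k <- unclass(constants)
  writeLines(c(
    "# pcion association constants",
    "# units: m^3/mol",
    "scale = SI",
    sprintf("K_AH = %s", .fmt(k[["K_AH"]])),
    sprintf("K_AMe = %s", .fmt(k[["K_AMe"]])),
    sprintf("K_BOH = %s", .fmt(k[["K_BOH"]])),
    sprintf("K_BCl = %s", .fmt(k[["K_BCl"]]))
  ), path)
  invisible(path)
}
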