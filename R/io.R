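#' Read and validate a clinical table
#'
#' Tab-separated, UTF-8, header row. Mandatory columns: `patient_id`,
#' `arm`; recognised optional columns: `os_months`, `os_event`,
#' `pfs_months`, `pfs_event`, `best_response`, `pdl1_status`,
#' `sum_longest_diameters_mm`, `n_metastatic_sites`, `stk11_keap1_mut`,
#' `original_btmb_high`. Enums are matched case-insensitively and stored in
#' canonical case; missing values may be empty or `NA`. A PFS exceeding OS
#' when both are event-observed is accepted with a warning (registry data
#' contain such records); duplicate patient ids are an error.
#'
#' @param path TSV file path.
#' @return validated clinical data frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_raw(path)
  for (col in c("patient_id", "arm"))
    if (!col %in% names(df))
      stop_ctb("clinical table missing mandatory column '%s'", col,
               class = "ctb_validation_error")
  if (anyNA(df$patient_id) || any(trimws(df$patient_id) == ""))
    stop_ctb("clinical table: missing patient_id", class = "ctb_validation_error")
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop_ctb("clinical table: duplicate patient_id: %s",
             paste(unique(dup), collapse = ", "),
             class = "ctb_validation_error")
  out <- data.frame(patient_id = df$patient_id, stringsAsFactors = FALSE)
  out$arm <- match_enum(df$arm, c("ICI", "comparator"), "arm", allow_na = FALSE)
  num_cols <- c("os_months", "pfs_months", "sum_longest_diameters_mm")
  for (col in num_cols)
    if (col %in% names(df)) {
      out[[col]] <- as_num(df[[col]], col)
      if (any(out[[col]] < 0, na.rm = TRUE))
        stop_ctb("clinical table: negative %s", col,
                 class = "ctb_validation_error")
    }
  for (col in c("os_event", "pfs_event"))
    if (col %in% names(df)) out[[col]] <- as.integer(as_bool(df[[col]], col))
  if ("n_metastatic_sites" %in% names(df))
    out$n_metastatic_sites <- as.integer(as_num(df$n_metastatic_sites,
                                                "n_metastatic_sites"))
  if ("best_response" %in% names(df))
    out$best_response <- match_enum(df$best_response,
                                    c("CR", "PR", "SD", "PD", "NE"),
                                    "best_response")
  if ("pdl1_status" %in% names(df))
    out$pdl1_status <- match_enum(df$pdl1_status,
                                  c("negative", "positive", "unknown"),
                                  "pdl1_status")
  for (col in c("stk11_keap1_mut", "original_btmb_high"))
    if (col %in% names(df)) out[[col]] <- as_bool(df[[col]], col)

  if (all(c("os_months", "os_event", "pfs_months", "pfs_event") %in% names(out))) {
    bad <- which(out$pfs_event == 1L & out$os_event == 1L &
                   out$pfs_months > out$os_months)
    if (length(bad))
      warning(sprintf(
        "clinical table: PFS > OS with both events at row(s) %s (accepted)",
        paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a somatic variant table (MAF-like TSV or VCF)
#'
#' The MAF-like TSV carries columns `patient_id`, `chrom`, `pos`, `ref`,
#' `alt`, `allele_fraction`, `depth`, `variant_class`, `driver_flag`,
#' `germline_flag`. For VCF input (4.x, possibly multi-sample; sample names
#' are taken as patient ids) the allele fraction comes from the per-sample
#' FORMAT field `AF`, or failing that is computed as
#' `AD_alt / (AD_ref + sum(AD_alt))`; multi-allelic records are split into
#' one call per alternate allele. VCF coordinates are kept 1-based. INFO
#' flags `DRIVER` and `GERMLINE`, when present, populate the corresponding
#' flags; otherwise both default to `FALSE`.
#'
#' @param path input file.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @return data frame of validated variant calls.
#' @export
read_variants <- function(path, format = c("maf_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "maf_tsv") read_variants_maf(path) else read_variants_vcf(path)
}

validate_variants <- function(out) {
  if (any(out$allele_fraction < 0 | out$allele_fraction > 1, na.rm = TRUE))
    stop_ctb("variant table: allele_fraction outside [0, 1]",
             class = "ctb_validation_error")
  if (any(out$depth < 0, na.rm = TRUE))
    stop_ctb("variant table: negative depth", class = "ctb_validation_error")
  if (any(out$pos < 1, na.rm = TRUE))
    stop_ctb("variant table: pos must be >= 1", class = "ctb_validation_error")
  out
}

read_variants_maf <- function(path) {
  df <- read_tsv_raw(path)
  needed <- c("patient_id", "chrom", "pos", "ref", "alt", "allele_fraction")
  for (col in needed)
    if (!col %in% names(df))
      stop_ctb("variant table missing mandatory column '%s'", col,
               class = "ctb_validation_error")
  out <- data.frame(
    patient_id = df$patient_id, chrom = df$chrom,
    pos = as.integer(as_num(df$pos, "pos")),
    ref = df$ref, alt = df$alt,
    allele_fraction = as_num(df$allele_fraction, "allele_fraction"),
    depth = if ("depth" %in% names(df))
      as.integer(as_num(df$depth, "depth")) else NA_integer_,
    variant_class = if ("variant_class" %in% names(df))
      match_enum(df$variant_class, c("SNV", "insertion", "deletion", "other"),
                 "variant_class")
      else infer_variant_class(df$ref, df$alt),
    driver_flag = if ("driver_flag" %in% names(df))
      isTRUE_vec(as_bool(df$driver_flag, "driver_flag")) else FALSE,
    germline_flag = if ("germline_flag" %in% names(df))
      isTRUE_vec(as_bool(df$germline_flag, "germline_flag")) else FALSE,
    stringsAsFactors = FALSE)
  validate_variants(out)
}

infer_variant_class <- function(ref, alt) {
  nr <- nchar(ref); na_ <- nchar(alt)
  ifelse(nr == 1 & na_ == 1, "SNV",
         ifelse(na_ > nr, "insertion", ifelse(nr > na_, "deletion", "other")))
}

read_variants_vcf <- function(path) {
  if (!file.exists(path)) stop_ctb("file not found: %s", path,
                                   class = "ctb_io_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(validate_variants(data.frame(
      patient_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), allele_fraction = numeric(),
      depth = integer(), variant_class = character(),
      driver_flag = logical(), germline_flag = logical(),
      stringsAsFactors = FALSE)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop_ctb("VCF has no sample columns", class = "ctb_format_error")
  samples <- colnames(gt)[-1]
  fmt_keys <- strsplit(gt[, 1], ":", fixed = TRUE)
  info <- fix$INFO
  has_flag <- function(flag) {
    if (is.null(info)) rep(FALSE, nrow(fix))
    else grepl(paste0("(^|;)", flag, "($|;|=)"), info)
  }
  driver_rec <- has_flag("DRIVER")
  germline_rec <- has_flag("GERMLINE")

  rows <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    keys <- fmt_keys[[r]]
    i_af <- match("AF", keys); i_ad <- match("AD", keys)
    if (is.na(i_af) && is.na(i_ad))
      stop_ctb("VCF record %s:%s has no AF or AD FORMAT field",
               fix$CHROM[r], fix$POS[r], class = "ctb_format_error")
    i_dp <- match("DP", keys)
    for (s in samples) {
      val <- gt[r, s]
      if (is.na(val) || val == "." || val == "") next
      parts <- strsplit(val, ":", fixed = TRUE)[[1]]
      field <- function(i) if (!is.na(i) && length(parts) >= i &&
                                 parts[i] != "." && parts[i] != "") parts[i]
      afs <- NULL; depth <- NA_integer_
      ad_str <- field(i_ad)
      if (!is.null(ad_str)) {
        ad <- suppressWarnings(as.numeric(
          strsplit(ad_str, ",", fixed = TRUE)[[1]]))
        tot <- sum(ad)
        if (is.finite(tot) && tot > 0) {
          afs <- ad[-1] / tot
          depth <- as.integer(round(tot))
        }
      }
      af_str <- field(i_af)
      if (!is.null(af_str)) {
        # assay-reported AF takes precedence over the AD-derived fraction
        afs <- suppressWarnings(as.numeric(
          strsplit(af_str, ",", fixed = TRUE)[[1]]))
      }
      if (is.null(afs)) next
      if (!is.na(i_dp) && length(parts) >= i_dp && parts[i_dp] != ".")
        depth <- suppressWarnings(as.integer(parts[i_dp]))
      if (length(afs) < length(alts)) afs <- rep_len(afs, length(alts))
      for (k in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = s, chrom = fix$CHROM[r],
          pos = as.integer(fix$POS[r]), ref = fix$REF[r], alt = alts[k],
          allele_fraction = afs[k], depth = depth,
          variant_class = infer_variant_class(fix$REF[r], alts[k]),
          driver_flag = driver_rec[r], germline_flag = germline_rec[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    stop_ctb("VCF yielded no calls with an allele-fraction source",
             class = "ctb_format_error")
  validate_variants(do.call(rbind, rows))
}

#' Read a plasma cfDNA input-mass table
#'
#' TSV with columns `patient_id` and `cfdna_input_mass_ng` (> 0).
#'
#' @param path TSV file path.
#' @return validated plasma data frame.
#' @export
read_plasma <- function(path) {
  df <- read_tsv_raw(path)
  for (col in c("patient_id", "cfdna_input_mass_ng"))
    if (!col %in% names(df))
      stop_ctb("plasma table missing mandatory column '%s'", col,
               class = "ctb_validation_error")
  mass <- as_num(df$cfdna_input_mass_ng, "cfdna_input_mass_ng")
  bad <- which(is.na(mass) | mass <= 0)
  if (length(bad))
    stop_ctb("plasma table: nonpositive/missing mass at row(s) %s",
             paste(utils::head(bad, 5L), collapse = ", "),
             class = "ctb_validation_error")
  data.frame(patient_id = df$patient_id, cfdna_input_mass_ng = mass,
             stringsAsFactors = FALSE)
}

run_config_known_keys <- c(
  "clinical", "variants", "plasma", "variant_format", "panel_size_mb",
  "af_floor", "include_indels", "exclude_germline",
  "exclude_drivers_from_btmb", "mean_af_variant_set", "zero_mass_policy",
  "epsilon_mass_ng", "dcb_indeterminate", "cutoff", "cutoff_arm",
  "ties_method", "rcs_knots", "subgroups", "out_dir", "seed")

#' Read and validate a structured run configuration (YAML)
#'
#' Recognised keys: input paths (`clinical`, `variants`, `plasma`,
#' `variant_format`), scoring policy knobs (`panel_size_mb`, `af_floor`,
#' `include_indels`, `exclude_germline`, `exclude_drivers_from_btmb`,
#' `mean_af_variant_set`, `zero_mass_policy`, `epsilon_mass_ng`,
#' `dcb_indeterminate`), analysis settings (`cutoff` -- a number or the
#' string `"derive"`; `cutoff_arm` -- `"ici"` or `"all"`; `ties_method`;
#' `rcs_knots`; `subgroups` -- named filter expressions over clinical
#' columns), and `out_dir` / `seed`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return named list of validated settings (class `ctb_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_known_keys)
  if (length(unknown))
    stop_ctb("run config: unknown key(s): %s",
             paste(unknown, collapse = ", "), class = "ctb_config_error")
  defaults <- list(variant_format = "maf_tsv", panel_size_mb = 1.0,
                   cutoff = "derive", cutoff_arm = "ici",
                   ties_method = "efron", rcs_knots = 4, seed = 1,
                   subgroups = list())
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$variant_format %in% c("maf_tsv", "vcf"))
    stop_ctb("run config: variant_format must be maf_tsv or vcf",
             class = "ctb_config_error")
  if (!cfg$cutoff_arm %in% c("ici", "all"))
    stop_ctb("run config: cutoff_arm must be ici or all",
             class = "ctb_config_error")
  if (!cfg$ties_method %in% c("efron", "breslow"))
    stop_ctb("run config: ties_method must be efron or breslow",
             class = "ctb_config_error")
  if (!(identical(cfg$cutoff, "derive") ||
        (is.numeric(cfg$cutoff) && length(cfg$cutoff) == 1L)))
    stop_ctb("run config: cutoff must be a number or \"derive\"",
             class = "ctb_config_error")
  structure(cfg, class = "ctb_run_config")
}

#' Write analysis artifacts and a checksum manifest
#'
#' Writes every artifact in `artifacts` into `out_dir`: data frames as TSV
#' (full numeric precision), lists as JSON, character vectors as plain
#' text. Returns (and writes) `manifest.tsv` listing each file with its MD5
#' checksum.
#'
#' @param artifacts named list; names become file names (extension chosen
#'   by type unless already present).
#' @param out_dir output directory.
#' @return data frame manifest (file, md5), invisibly.
#' @export
write_results <- function(artifacts, out_dir) {
  if (is.null(names(artifacts)) || any(names(artifacts) == ""))
    stop_ctb("write_results: artifacts must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_ctb("write_results: cannot create directory %s", out_dir,
             class = "ctb_io_error")
  files <- character()
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    if (is.data.frame(a)) {
      f <- file.path(out_dir, ensure_ext(nm, "tsv"))
      write_tsv_full(a, f)
    } else if (is.list(a)) {
      f <- file.path(out_dir, ensure_ext(nm, "json"))
      jsonlite::write_json(a, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
    } else {
      f <- file.path(out_dir, ensure_ext(nm, "txt"))
      writeLines(as.character(a), f)
    }
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

ensure_ext <- function(nm, ext) {
  if (grepl("\\.[A-Za-z0-9]+$", nm)) nm else paste0(nm, ".", ext)
}
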