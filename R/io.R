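# File interchange: dosage TSV, minimal GT-only VCF, weight/rate/
# distribution tables, run configuration, and output writing with
# provenance headers.

# Missing values are written as "." in all delimited files.
NA_TOKEN <- "."

provenance_header <- function(seed = NA, config_hash = NA) {
  version <- as.character(utils::packageVersion("crcrisk"))
  sprintf("# crcrisk %s | seed=%s | config=%s", version,
          ifelse(is.na(seed), "none", seed),
          ifelse(is.na(config_hash), "none", config_hash))
}

# Write a data.frame with a provenance comment line; readers skip "#".
write_output_table <- function(x, path, sep = ",", seed = NA,
                               config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.table(x, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = NA_TOKEN)
  invisible(path)
}

read_delim_skip <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    na.strings = NA_TOKEN, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Plain-text interchange format: one row per subject, first column
#' `subject_id`, then one column per SNP with dosages 0/1/2 and `.` for
#' missing.
#'
#' @param genotypes integer dosage matrix with subject rownames and SNP
#'   colnames.
#' @param path file path.
#' @return `write_dosage_tsv` the path (invisibly); `read_dosage_tsv`
#'   the dosage matrix.
#' @export
write_dosage_tsv <- function(genotypes, path, ...) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_output_table(df, path, sep = "\t", ...)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_delim_skip(path, sep = "\t")
  g <- as.matrix(df[, -1, drop = FALSE])
  mode(g) <- "integer"
  rownames(g) <- df$subject_id
  g
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file carrying only unphased GT fields, one sample
#' column per subject and one biallelic record per SNP. The risk allele
#' is written as ALT; REF is an arbitrary different nucleotide (the
#' coordinates are identifiers, not mapped positions). Missing dosages
#' become `./.`.
#'
#' @param genotypes dosage matrix (risk-allele copies).
#' @param panel [snp_panel()] supplying identifiers and risk alleles.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, panel, path) {
  stopifnot(inherits(panel, "snp_panel"),
            identical(colnames(genotypes), panel$snp_id))
  other <- function(a) c(A = "G", C = "T", G = "A", T = "C")[[a]]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=crcrisk",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(panel))) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c("1", j, panel$snp_id[j],
                       other(panel$risk_allele[j]), panel$risk_allele[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF into risk-allele dosages
#'
#' Parses a VCF (GT field, biallelic records only) and converts each
#' genotype to a dosage of the risk allele named in the weights table:
#' the ALT count when the risk allele is ALT, its complement when the
#' risk allele is REF. `./.` becomes `NA`.
#'
#' @param path VCF file path.
#' @param weights `data.frame` with `id` and `risk_allele` (as read by
#'   [read_weights()]); rows are matched to VCF records by ID.
#' @return List with `genotypes` (subjects x SNPs dosage matrix) and
#'   `records` (`data.frame` of id, ref, alt).
#' @export
read_vcf_genotypes <- function(path, weights) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("unsupported record: multiallelic site(s) ",
         paste(fix$ID[grepl(",", fix$ALT, fixed = TRUE)], collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = variants, cols = samples; count ALT alleles
  alt_count <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
             sum(a == "1")
           }, integer(1)))
  }
  dos_alt <- t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) dos_alt <- t(dos_alt)
  colnames(dos_alt) <- colnames(gt)
  m <- match(fix$ID, weights$id)
  if (anyNA(m)) {
    stop("weights table lacks SNP(s): ",
         paste(fix$ID[is.na(m)], collapse = ", "), call. = FALSE)
  }
  risk <- toupper(weights$risk_allele[m])
  dos <- matrix(NA_integer_, nrow = ncol(dos_alt), ncol = nrow(fix),
                dimnames = list(colnames(dos_alt), fix$ID))
  for (i in seq_len(nrow(fix))) {
    if (risk[i] == toupper(fix$ALT[i])) {
      dos[, i] <- dos_alt[i, ]
    } else if (risk[i] == toupper(fix$REF[i])) {
      dos[, i] <- 2L - dos_alt[i, ]
    } else {
      stop("allele mismatch for ", fix$ID[i], ": risk allele ", risk[i],
           " matches neither REF ", fix$REF[i], " nor ALT ", fix$ALT[i],
           call. = FALSE)
    }
  }
  list(genotypes = dos,
       records = data.frame(id = fix$ID, ref = fix$REF, alt = fix$ALT,
                            stringsAsFactors = FALSE))
}

#' Write / read a weight table (SNP panel or lifestyle weights) as TSV
#'
#' Columns: `id`, `risk_allele` (SNP panels only), `beta`, and for SNP
#' panels optionally `raf` and `inbreeding_f`.
#'
#' @param x a [snp_panel()] or [weight_vector()].
#' @param path file path.
#' @return `write_weights` the path (invisibly); `read_weights` a
#'   `data.frame`, or a [snp_panel()] when allele and frequency columns
#'   are present (`as_panel = TRUE`).
#' @export
write_weights <- function(x, path, ...) {
  if (inherits(x, "snp_panel")) {
    df <- data.frame(id = x$snp_id, risk_allele = x$risk_allele,
                     beta = x$weight, raf = x$raf,
                     inbreeding_f = x$inbreeding_f,
                     stringsAsFactors = FALSE)
  } else if (inherits(x, "weight_vector")) {
    df <- data.frame(id = names(x), beta = as.numeric(x),
                     stringsAsFactors = FALSE)
  } else stop("x must be a snp_panel or weight_vector", call. = FALSE)
  write_output_table(df, path, sep = "\t", ...)
}

#' @rdname write_weights
#' @param as_panel coerce to [snp_panel()] (requires `risk_allele` and
#'   `raf` columns).
#' @export
read_weights <- function(path, as_panel = FALSE) {
  df <- read_delim_skip(path, sep = "\t")
  if (as_panel) {
    f <- if ("inbreeding_f" %in% names(df)) df$inbreeding_f else 0
    return(snp_panel(df$id, df$risk_allele, df$raf, df$beta, f))
  }
  df
}

#' Write / read an age-banded rate table as CSV
#'
#' Columns: `sex`, `age_start`, `age_end`, `incidence_per_100k`,
#' `mortality_per_100k`. Hazards are converted to per person-year on
#' read.
#'
#' @param rates a [rate_table()].
#' @param path file path.
#' @export
write_rate_table <- function(rates, path, ...) {
  stopifnot(inherits(rates, "rate_table"))
  df <- data.frame(sex = rates$sex, age_start = rates$age_start,
                   age_end = rates$age_end,
                   incidence_per_100k = rates$incidence * 1e5,
                   mortality_per_100k = rates$mortality * 1e5,
                   stringsAsFactors = FALSE)
  write_output_table(df, path, ...)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  df <- read_delim_skip(path)
  rate_table(df$age_start, df$age_end, df$incidence_per_100k,
             df$mortality_per_100k, sex = df$sex[1], per100k = TRUE)
}

#' Write / read a risk-profile distribution as CSV
#'
#' Columns: `sex`, optional `age_start`/`age_end`, `profile`,
#' `prevalence`, `rr`, `se_log_rr`.
#'
#' @param dist a [risk_distribution()].
#' @param path file path.
#' @export
write_risk_distribution <- function(dist, path, ...) {
  stopifnot(inherits(dist, "risk_distribution"))
  write_output_table(as.data.frame(dist), path, ...)
}

#' @rdname write_risk_distribution
#' @export
read_risk_distribution <- function(path) {
  df <- read_delim_skip(path)
  risk_distribution(df$profile, df$prevalence, df$rr,
                    se_log_rr = if ("se_log_rr" %in% names(df)) {
                      df$se_log_rr
                    } else NA_real_,
                    age_start = df$age_start, age_end = df$age_end,
                    sex = if ("sex" %in% names(df)) df$sex[1] else NA)
}

#' Write / read a subject table as CSV
#'
#' @param subjects cohort `data.frame`.
#' @param path file path.
#' @export
write_subjects <- function(subjects, path, ...) {
  write_output_table(as.data.frame(subjects), path, ...)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- read_delim_skip(path)
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = c("male", "female"))
  }
  if ("outcome" %in% names(df)) {
    df$outcome <- factor(df$outcome,
                         levels = c("control", "non_advanced", "advanced"))
  }
  if ("fit_positive" %in% names(df)) {
    df$fit_positive <- as.logical(df$fit_positive)
  }
  class(df) <- c("crc_cohort", "data.frame")
  df
}

#' Read a run configuration (YAML)
#'
#' The configuration names the requested pipeline stages, input paths,
#' analysis parameters and the output directory. Validation happens
#' before any computation: every referenced input path must exist, and a
#' requested stage whose inputs are absent raises a configuration error.
#'
#' @param path YAML file path.
#' @return List of class `run_config`; `config_hash` carries the MD5 of
#'   the file for provenance headers.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_hash <- unname(tools::md5sum(path))
  validate_run_config(cfg)
}

#' Validate and normalize a run configuration
#'
#' @param cfg configuration list (see [read_run_config()]).
#' @return The normalized configuration, class `run_config`.
#' @export
validate_run_config <- function(cfg) {
  has_rates <- !is.null(cfg$inputs$rates) &&
    !is.null(cfg$inputs$risk_distribution)
  defaults <- list(
    seed = 1L,
    # the project stage needs rate inputs, so it enters the default
    # stage list only when they are configured
    stages = c("simulate", "score", "associate",
               if (has_rates) "project", "screen"),
    n_subjects = 2000L,
    out_dir = "crcrisk-output",
    inputs = list(),
    hwe_alpha = 0.05,
    quantile_type = 7,
    lifestyle_scheme = "sex_median",
    prs_scheme = "percentile_90",
    triage = "either-high",
    adjust = "age",
    n_boot = 500L,
    age = 50,
    horizon = 10,
    fit_threshold = 100)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  known <- c("simulate", "score", "associate", "project", "screen")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("project" %in% cfg$stages &&
      (is.null(cfg$inputs$rates) || is.null(cfg$inputs$risk_distribution))) {
    stop("config error: project stage requires inputs$rates and ",
         "inputs$risk_distribution", call. = FALSE)
  }
  if (!"simulate" %in% cfg$stages &&
      is.null(cfg$inputs$subjects)) {
    stop("config error: either request the simulate stage or provide ",
         "inputs$subjects", call. = FALSE)
  }
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) {
      stop("config error: input path does not exist: ", p, call. = FALSE)
    }
  }
  if (is.null(cfg$config_hash)) cfg$config_hash <- NA_character_
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end risk-modelling pipeline
#'
#' Executes the requested stages in order - simulate (or load) the
#' cohort, construct and categorize scores, estimate odds ratios,
#' project absolute risks, evaluate screening scenarios - writing every
#' table under `out_dir` with a provenance header (package version,
#' seed, config hash) and a `run.log`. A fixed seed and config give a
#' byte-identical output bundle.
#'
#' @param config a `run_config` (from [read_run_config()] or
#'   [validate_run_config()]).
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(provenance_header(config$seed, config$config_hash))
  log_note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  results <- list()
  hdr <- list(seed = config$seed, config_hash = config$config_hash)
  emit <- function(x, name, sep = ",") {
    path <- file.path(config$out_dir, name)
    write_output_table(x, path, sep = sep, seed = hdr$seed,
                       config_hash = hdr$config_hash)
    log_note("wrote ", name)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- cohort ---------------------------------------------------------
  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      panel <- if (!is.null(config$inputs$weights_prs)) {
        read_weights(config$inputs$weights_prs, as_panel = TRUE)
      } else default_snp_panel()
      cc <- cohort_config(n_subjects = config$n_subjects,
                          seed = config$seed)
      subjects <- simulate_subjects(cc, panel)
      results$panel <- panel
      results$subjects <- subjects
      emit(subjects, "subjects.csv")
      g <- as.matrix(subjects[, panel$snp_id, drop = FALSE])
      rownames(g) <- subjects$subject_id
      write_dosage_tsv(g, file.path(config$out_dir, "genotypes.tsv"),
                       seed = hdr$seed, config_hash = hdr$config_hash)
      write_vcf_genotypes(g, panel,
                          file.path(config$out_dir, "genotypes.vcf"))
      write_weights(panel, file.path(config$out_dir, "snp_panel.tsv"),
                    seed = hdr$seed, config_hash = hdr$config_hash)
      log_note("simulated cohort: n=", nrow(subjects),
               ", SNPs=", nrow(panel), ", seed=", config$seed)
    })
  } else {
    run_stage("load", {
      results$subjects <- read_subjects(config$inputs$subjects)
      if (!is.null(config$inputs$weights_prs)) {
        results$panel <- read_weights(config$inputs$weights_prs,
                                       as_panel = TRUE)
      }
      if (!is.null(config$inputs$genotypes)) {
        g <- if (grepl("\\.vcf$", config$inputs$genotypes)) {
          read_vcf_genotypes(config$inputs$genotypes,
                             read_weights(config$inputs$weights_prs)
          )$genotypes
        } else read_dosage_tsv(config$inputs$genotypes)
        m <- match(results$subjects$subject_id, rownames(g))
        for (snp in colnames(g)) {
          results$subjects[[snp]] <- g[m, snp]
        }
      }
      log_note("loaded cohort: n=", nrow(results$subjects))
    })
  }

  # --- scores ---------------------------------------------------------
  if ("score" %in% config$stages) {
    run_stage("score", {
      subjects <- results$subjects
      panel <- results$panel
      g <- as.matrix(subjects[, panel$snp_id, drop = FALSE])
      rownames(g) <- subjects$subject_id
      filt <- filter_snps(panel, g, alpha = config$hwe_alpha)
      emit(filt$report, "hwe_report.tsv", sep = "\t")
      prs <- polygenic_score(g, filt$panel)
      lw <- fit_lifestyle_weights(subjects)
      ls <- lifestyle_score(subjects, lw$male, lw$female)
      scored <- !is.na(prs)
      if (any(!scored)) {
        log_note("dropped ", sum(!scored),
                 " subject(s) with failed SNP detection before scoring")
      }
      subjects <- subjects[scored, , drop = FALSE]
      prs <- prs[scored]
      ls <- ls[scored]
      lifestyle_group <- categorize(ls, config$lifestyle_scheme,
                                    sex = subjects$sex,
                                    quantile_type = config$quantile_type)
      prs_group <- categorize(prs, config$prs_scheme,
                              quantile_type = config$quantile_type)
      results$panel_retained <- filt$panel
      results$hwe_report <- filt$report
      results$subjects <- subjects
      results$scores <- data.frame(subject_id = subjects$subject_id,
                                    lifestyle_score = ls,
                                    prs = unname(prs),
                                    lifestyle_group = lifestyle_group,
                                    prs_group = prs_group,
                                    stringsAsFactors = FALSE)
      emit(results$scores, "scores.csv")
      log_note("retained ", nrow(filt$panel), "/", nrow(panel),
               " SNPs after HWE filter (alpha=", config$hwe_alpha, ")")
    })
  }

  # --- association ----------------------------------------------------
  if ("associate" %in% config$stages) {
    run_stage("associate", {
      or_table <- run_contrast_suite(results$subjects,
                                     results$scores$lifestyle_group,
                                     results$scores$prs_group,
                                     adjust = config$adjust)
      results$or_table <- or_table
      emit(or_table, "odds_ratios.csv")
    })
  }

  # --- absolute risk --------------------------------------------------
  if ("project" %in% config$stages) {
    run_stage("project", {
      rates <- read_rate_table(config$inputs$rates)
      dist <- read_risk_distribution(config$inputs$risk_distribution)
      abs_risk <- project_profile_table(config$age, config$horizon,
                                        dist, rates,
                                        n_boot = config$n_boot,
                                        seed = config$seed)
      results$absolute_risk <- abs_risk
      emit(abs_risk, "absolute_risk.csv")
    })
  }

  # --- screening yield ------------------------------------------------
  if ("screen" %in% config$stages) {
    run_stage("screen", {
      rules <- lapply(config$triage, triage_rule)
      yield <- compare_scenarios(results$subjects,
                                 results$scores$lifestyle_group,
                                 results$scores$prs_group,
                                 rules = rules,
                                 fit_threshold = config$fit_threshold)
      results$yield <- yield
      emit(yield, "yield.csv")
    })
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(results)
}
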