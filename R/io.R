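#' Read a GWAS summary-statistics file
#'
#' Tab-separated, columns `SNP`, `CHR`, `BP`, `EA`, `NEA`, `EAF`, `BETA`,
#' `SE`, `P`, `N` (1-based positions, `EA` = effect allele, forward strand
#' assumed; comment lines start with `#`). Rows failing validation (allele
#' not A/C/G/T, EAF outside \[0,1\], non-positive SE, P outside (0,1\]) are
#' rejected with line-numbered messages; a missing mandatory column is an
#' error.
#'
#' @param path File path.
#' @return Tibble with tidy column names `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "triomr_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  mandatory <- c("SNP", "CHR", "BP", "EA", "NEA", "EAF", "BETA", "SE", "P", "N")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "triomr_io_error")
  }
  line <- seq_len(nrow(raw))
  problems <- character(0)
  flag <- function(bad, reason) {
    if (any(bad, na.rm = TRUE)) {
      problems <<- c(problems,
                     sprintf("line %d: %s", line[which(bad)], reason))
    }
    bad & !is.na(bad)
  }
  bad <- flag(!valid_allele(raw$EA) | !valid_allele(raw$NEA),
              "allele not in A/C/G/T")
  bad <- bad | flag(raw$EAF < 0 | raw$EAF > 1, "EAF outside [0, 1]")
  bad <- bad | flag(raw$SE <= 0, "nonpositive SE")
  bad <- bad | flag(raw$P <= 0 | raw$P > 1, "P outside (0, 1]")
  if (length(problems)) {
    warn(paste0("Rejected ", sum(bad), " malformed row(s):\n",
                paste(problems, collapse = "\n")))
  }
  raw <- raw[!bad, , drop = FALSE]
  tibble::tibble(
    id = as.character(raw$SNP), chrom = raw$CHR, pos = raw$BP,
    effect_allele = toupper(raw$EA), other_allele = toupper(raw$NEA),
    eaf = raw$EAF, beta = raw$BETA, se = raw$SE, p = raw$P, n = raw$N
  )
}

#' Write a GWAS summary-statistics file
#'
#' Inverse of [read_summary_stats()]; prepends a comment header recording the
#' seed and config hash when given.
#'
#' @param stats Tibble in the tidy layout of [read_summary_stats()].
#' @param path Output path.
#' @param seed,config_hash Optional provenance recorded in the header.
#' @export
write_summary_stats <- function(stats, path, seed = NULL, config_hash = NULL) {
  out <- tibble::tibble(
    SNP = stats$id, CHR = stats$chrom, BP = stats$pos,
    EA = stats$effect_allele, NEA = stats$other_allele,
    EAF = stats$eaf, BETA = stats$beta, SE = stats$se, P = stats$p,
    N = stats$n
  )
  write_results(out, path, seed = seed, config_hash = config_hash)
}

#' Write a results table with a provenance header
#'
#' Deterministic column order (as supplied), floats serialized at a fixed
#' number of significant digits, and a comment header carrying the seed and
#' configuration hash so every output file is traceable to its run.
#'
#' @param results Data frame.
#' @param path Output path.
#' @param digits Significant digits for floating-point columns (default 10).
#' @param seed,config_hash Optional provenance values for the header.
#' @export
write_results <- function(results, path, digits = 10, seed = NULL,
                          config_hash = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# triomr seed=%s config=%s",
                    seed %||% "NA", config_hash %||% "NA")
  fmt <- dplyr::mutate(as.data.frame(results),
                       dplyr::across(dplyr::where(is.double),
                                     ~ signif(.x, digits)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Write trio genotype matrices and phenotypes as TSV
#'
#' Genotypes are written families x variants with a header of variant ids;
#' phenotypes as a plain TSV; the simulation config as YAML with its seed.
#'
#' @param trios A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_trio_cohort <- function(trios, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- trios$config$seed
  h <- config_hash(trios$config)
  files <- c(
    dosage_m = file.path(dir, "dosage_maternal.tsv"),
    dosage_f = file.path(dir, "dosage_paternal.tsv"),
    dosage_o = file.path(dir, "dosage_offspring.tsv"),
    variants = file.path(dir, "variants.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    config = file.path(dir, "config.yaml")
  )
  for (nm in c("dosage_m", "dosage_f", "dosage_o")) {
    write_results(as.data.frame(trios[[nm]]), files[[nm]], seed = seed,
                  config_hash = h)
  }
  write_results(trios$variants, files[["variants"]], seed = seed,
                config_hash = h)
  if (!is.null(trios$phenos)) {
    write_results(trios$phenos, files[["phenotypes"]], seed = seed,
                  config_hash = h)
  }
  write_sim_config(trios$config, files[["config"]])
  invisible(files)
}

#' @rdname write_trio_cohort
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$ld <- if (!is.null(lst$ld)) as.vector(lst$ld)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_trio_cohort
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  m <- lst$m
  ld <- if (!is.null(lst$ld)) matrix(unlist(lst$ld), m, m)
  do.call(sim_config, c(
    lst[intersect(names(lst), setdiff(names(formals(sim_config)), "ld"))],
    list(ld = ld)
  ))
}

# stable short hash of a config (polynomial rolling hash of its serialized text)
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 12)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
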