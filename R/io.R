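#' Read a FASTA file
#'
#' Accepts DNA or protein FASTA with `>` headers and optionally wrapped
#' sequence lines.
#'
#' @param path FASTA file.
#' @return list of records, each `list(id, desc, seq)`; `id` is the first
#'   whitespace-delimited token of the header, `desc` the full header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0) return(list())
  first <- content[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: line %d does not start with '>'", first))
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(k) {
    hdr <- names(set)[k]
    list(id = strsplit(hdr, "\\s+")[[1]][1], desc = hdr,
         seq = as.character(set[[k]]))
  })
}

#' Read spectra from CSV
#'
#' Expected layout: first column `wavelength_nm`, one column per spectrum
#' with a sample identifier in the header; `#` lines are comments.
#'
#' @param path CSV file.
#' @param kind spectrum kind assigned to every column.
#' @return named list of [spectrum()]s.
#' @export
read_spectra_csv <- function(path, kind = "reflectance") {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(tab)[1] != "wavelength_nm")
    stop("malformed spectra CSV (line 1): first column must be 'wavelength_nm'")
  wl <- tab[[1]]
  out <- lapply(names(tab)[-1], function(nm) spectrum(wl, tab[[nm]], kind = kind))
  names(out) <- names(tab)[-1]
  out
}

#' Write spectra to CSV
#'
#' @param spectra named list of [spectrum()]s on a common grid.
#' @param path output file.
#' @export
write_spectra_csv <- function(spectra, path) {
  wl <- spectra[[1]]$wl
  tab <- data.frame(wavelength_nm = wl)
  for (nm in names(spectra)) {
    if (length(spectra[[nm]]$wl) != length(wl) || any(spectra[[nm]]$wl != wl))
      stop("spectra are on different grids")
    tab[[nm]] <- spectra[[nm]]$values
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param table data.frame.
#' @param path output file.
#' @param digits significant digits for numeric columns (`NA` = full
#'   precision).
#' @export
write_tsv <- function(table, path, digits = 6) {
  if (!is.na(digits))
    for (j in seq_along(table))
      if (is.numeric(table[[j]])) table[[j]] <- signif(table[[j]], digits)
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis end to end
#'
#' Orchestrates the pipeline on seeded synthetic data: ring generation,
#' pairwise JND tables and comimic-vs-conspecific ANOVAs for the
#' requested visual systems, SWS1 classification of the packaged
#' sequence windows, and the mate-choice GLM on simulated trials. Writes
#' one TSV per stage plus a run log.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param systems visual-system preset names to run.
#' @param scenario a ring scenario, as from [ring_scenario()]; default is
#'   the package's calibrated demonstration scenario.
#' @param jnd_threshold JND discriminability threshold.
#' @return invisible list with the per-stage tables.
#' @export
run_full_analysis <- function(out_dir, seed = 1,
                              systems = c("bluetit-uvs", "peafowl-vs"),
                              scenario = NULL, jnd_threshold = 3.00) {
  known <- unique(read_preset_table()$preset)
  bad <- setdiff(systems, known)
  if (length(bad))
    stop("configuration error: unknown preset(s) ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stamp <- function(stage, msg) {
    line <- sprintf("[%s] seed=%d %s", stage, seed, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (is.null(scenario))
    scenario <- ring_scenario(seed = seed)
  stamp("config", sprintf("systems=%s threshold=%g",
                          paste(systems, collapse = ","), jnd_threshold))

  anova_rows <- list(); jnd_tabs <- list()
  for (sys_name in systems) {
    sys <- build_preset(sys_name)
    ring <- generate_ring(scenario, sys)
    recs <- pairwise_jnd_table(ring$measurements, sys)
    means <- individual_mean_jnd(recs)
    for (st in unique(means$stratum)) {
      a <- comimic_vs_conspecific_anova(means[means$stratum == st, ])
      anova_rows[[length(anova_rows) + 1]] <- data.frame(
        system = sys_name, stratum = st,
        mean_comimic = mean(means$mean_comimic[means$stratum == st]),
        mean_conspecific = mean(means$mean_conspecific[means$stratum == st]),
        F = a$F, df_num = a$df_num, df_den = a$df_den, p = a$p,
        frac_discriminable = {
          rs <- recs[paste(recs$patch_color, recs$wing_side, sep = "/") == st, ]
          mean(rs$jnd[rs$pair_type == "comimic"] > jnd_threshold)
        })
    }
    recs$system <- sys_name
    jnd_tabs[[sys_name]] <- recs
    stamp("jnd", sprintf("system=%s pairs=%d", sys_name, nrow(recs)))
  }
  jnd_table <- do.call(rbind, jnd_tabs)
  anova_table <- do.call(rbind, anova_rows)
  write_tsv(jnd_table, file.path(out_dir, "pairwise_jnd.tsv"))
  write_tsv(anova_table, file.path(out_dir, "comimic_anova.tsv"))

  fasta <- system.file("extdata", "sws1_windows.fasta", package = "mimicolor")
  calls <- classify_fasta(fasta)
  write_tsv(calls, file.path(out_dir, "sws1_calls.tsv"))
  stamp("opsin", sprintf("records=%d UVS=%d", nrow(calls),
                         sum(calls$type == "UVS")))

  trials <- generate_mate_choice_trials(seed = seed + 1)
  choice <- build_choice_table(trials$trials, behavior = "approach")
  fit <- fit_weighted_binomial(choice, design = "treatment")
  glm_tab <- data.frame(term = names(fit$coefficients),
                        estimate = fit$coefficients, se = fit$standard_errors,
                        z = fit$z, p = fit$p)
  write_tsv(glm_tab, file.path(out_dir, "mate_choice_glm.tsv"))
  stamp("glm", sprintf("males=%d converged=%s", length(unique(choice$male_id)),
                       fit$converged))

  writeLines(c(sprintf("mimicolor %s", as.character(utils::packageVersion("mimicolor"))),
               log_lines), file.path(out_dir, "run_log.txt"))
  invisible(list(jnd = jnd_table, anova = anova_table, sws1 = calls,
                 mate_choice = glm_tab))
}
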