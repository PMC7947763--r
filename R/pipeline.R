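# Pipeline orchestration: entropy -> ASR -> substitution mapping ->
# phosphosite/OU -> property selection -> coevolution, from one
# configuration, with TSV stage outputs and a consolidated report.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full domain-evolution analysis
#'
#' Executes the analysis stages in dependency order on a supplied dataset
#' (alignment + tree + region configuration, and optionally a continuous
#' trait), writing per-stage TSVs under `out_dir` and returning a
#' consolidated report. All statistics in the report are re-derivable from
#' the stage outputs on disk.
#'
#' @param aln A [pld_alignment].
#' @param tree A rooted `"phylo"` matching the alignment taxa.
#' @param config A [region_config] (resolved or not).
#' @param trait Optional named numeric tip trait (e.g. fibril-core folding
#'   free energies); when `NULL` the phosphosite count trait is used for
#'   the drift-vs-selection stage.
#' @param out_dir Output directory for stage TSVs (created if needed);
#'   `NULL` skips writing.
#' @param model An [aa_model] (default JTT + Gamma, shape optimised by
#'   BIC against the equal-rates variant).
#' @param min_posterior Endpoint-support filter for event mapping.
#' @param clade Name of the focal clade in `config` for the
#'   creation/destruction and two-regime analyses (default: first clade).
#' @param distances Optional residue-pair distance table for the
#'   coevolution-distance correlation.
#' @param properties Property list for the selection scan (default
#'   [property_table()]).
#' @param exclude_phosphosites Exclude phosphosite columns from the
#'   property-selection scan (default TRUE).
#' @return List of class `pipeline_report`; see the elements written by
#'   each stage (`entropy`, `asr`, `events`, `toggles`, `phospho`, `ou`,
#'   `propsel`, `coevo`).
#' @export
run_pipeline <- function(aln, tree, config, trait = NULL, out_dir = NULL,
                         model = NULL, min_posterior = 0, clade = NULL,
                         distances = NULL, properties = NULL,
                         exclude_phosphosites = TRUE) {
  tree <- validate_tree(tree, aln)
  config <- resolve_config(config, aln)
  if (is.null(clade) && length(config$clades)) clade <- names(config$clades)[1]
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(x, name) if (!is.null(out_dir))
    write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
  report <- list()

  # --- conservation ---------------------------------------------------
  prof <- entropy_profile(aln)
  cons <- conserved_columns(aln)
  ent_tab <- data.frame(column = seq_len(aln$length),
                        entropy = prof$entropy,
                        n_effective = prof$n_effective,
                        conserved = seq_len(aln$length) %in% cons)
  emit(ent_tab, "entropy")
  sticker_ok <- all(config$sticker_columns %in%
                      conserved_columns(aln, residue = "Y"))
  report$entropy <- list(median = stats::median(prof$entropy, na.rm = TRUE),
                         n_conserved = length(cons),
                         stickers_all_conserved_Y = sticker_ok)

  # --- ancestral reconstruction --------------------------------------
  if (is.null(model)) {
    sel <- select_model_bic(aln, tree, list(aa_model("JTT"),
                                            aa_model("JTT", gamma_shape = 1)))
    model <- if (sel$gamma[1])
      aa_model("JTT", gamma_shape = sel$shape[1]) else aa_model("JTT")
    report$model_selection <- sel
  }
  recon <- marginal_ancestral_states(aln, tree, model)
  report$asr <- list(mean_map = recon$mean_map, sd_map = recon$sd_map,
                     loglik = recon$loglik)

  # --- substitution mapping ------------------------------------------
  events <- map_substitutions(recon, aln, min_posterior = min_posterior)
  emit(as.data.frame(events), "events")
  exch <- exchange_matrix(events)
  emit(as.data.frame.matrix(exch), "exchange_matrix")
  tog <- toggle_summary(exch)
  report$toggles <- tog

  # --- phosphosite trait + creation/destruction ----------------------
  ph <- phosphosite_trait(aln, config)
  emit(data.frame(taxon = names(ph), phosphosites = ph), "phosphosite_trait")
  report$phospho <- list(mean = mean(ph), range = range(ph))
  if (!is.null(clade)) {
    cd <- creation_destruction_table(events, config, clade)
    report$phospho$creation_destruction <- cd
  }

  # --- drift vs stabilizing selection --------------------------------
  ou_trait <- if (is.null(trait)) ph else trait
  fit_bm <- fit_trait_model(tree, ou_trait, model = "BM")
  fit_ou1 <- fit_trait_model(tree, ou_trait, model = "OU1")
  lrt1 <- compare_models(fit_bm, fit_ou1)
  report$ou <- list(bm = coef(fit_bm), ou1 = coef(fit_ou1),
                    bm_loglik = fit_bm$loglik, ou1_loglik = fit_ou1$loglik,
                    drift_vs_selection = lrt1)
  if (!is.null(clade)) {
    painting <- paint_regimes(tree, config$clades[clade])
    fit_ou2 <- fit_trait_model(tree, ou_trait, model = "OUk",
                               painting = painting)
    report$ou$ou2 <- coef(fit_ou2)
    report$ou$one_vs_two_optima <- compare_models(fit_ou1, fit_ou2)
  }
  ou_tab <- data.frame(model = c("BM", "OU1",
                                 if (!is.null(clade)) "OU2"),
                       loglik = c(fit_bm$loglik, fit_ou1$loglik,
                                  if (!is.null(clade)) fit_ou2$loglik))
  ou_tab$aic <- -2 * ou_tab$loglik +
    2 * c(2, 3, if (!is.null(clade)) 4)
  emit(ou_tab, "ou_fits")

  # --- property selection --------------------------------------------
  if (is.null(properties)) properties <- property_table()
  scan_cols <- seq_len(aln$length)
  if (exclude_phosphosites)
    scan_cols <- setdiff(scan_cols, config$phosphosite_columns)
  prop_rows <- list()
  strengths <- numeric()
  for (id in names(properties)) {
    bounds <- category_bounds(properties[[id]])
    p <- expected_distribution(aln, properties[[id]], bounds)
    O <- observed_distribution(events, properties[[id]], bounds,
                               columns = scan_cols)
    if (sum(O) == 0) next
    sc <- selection_scores(O, p)
    strengths[id] <- sc$strength
    prop_rows[[id]] <- data.frame(property = id, chisq = sc$chisq,
                                  p_value = sc$p_value,
                                  strength = sc$strength,
                                  n_events = sc$n_events)
  }
  prop_tab <- do.call(rbind, prop_rows)
  emit(prop_tab, "property_selection")
  report$propsel <- list(table = prop_tab)
  if (length(strengths) >= 2L)
    report$propsel$groups <- cluster_and_average(
      properties[names(strengths)], strengths)

  # --- coevolution ----------------------------------------------------
  bm <- binary_matrix(events, tree)
  coevo <- coevolution_scan(bm)
  emit(as.data.frame(coevo), "coevolution")
  report$coevo <- list(n_pairs = nrow(coevo),
                       n_flagged = sum(coevo$flagged),
                       top = utils::head(as.data.frame(coevo), 5L))
  if (!is.null(distances) && nrow(coevo) >= 3L)
    report$coevo$distance <- distance_correlation(coevo, distances)

  report$inputs <- list(n_taxa = length(aln$taxa), n_columns = aln$length,
                        model = model$name, gamma_shape = model$gamma_shape,
                        min_posterior = min_posterior)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Domain-evolution pipeline report\n")
  cat(sprintf("  alignment: %d taxa x %d columns; model %s\n",
              x$inputs$n_taxa, x$inputs$n_columns, x$inputs$model))
  cat(sprintf("  median entropy %.4f; %d conserved columns\n",
              x$entropy$median, x$entropy$n_conserved))
  cat(sprintf("  ASR mean MAP posterior %.3f +/- %.3f\n",
              x$asr$mean_map, x$asr$sd_map))
  cat(sprintf("  toggle events: %s (%.1f%% of %d)\n",
              paste(names(x$toggles$pair_counts), x$toggles$pair_counts,
                    sep = "=", collapse = ", "),
              100 * x$toggles$fraction, x$toggles$total_events))
  if (!is.null(x$phospho$creation_destruction)) {
    cd <- x$phospho$creation_destruction
    cat(sprintf("  creation/destruction: clade %.3g vs background %.3g (Fisher p = %.3g)\n",
                cd$ratio_clade, cd$ratio_background, cd$fisher_p))
  }
  cat(sprintf("  drift vs selection LRT p = %.3g\n",
              x$ou$drift_vs_selection$p_value))
  if (!is.null(x$ou$one_vs_two_optima))
    cat(sprintf("  one vs two optima LRT p = %.3g\n",
                x$ou$one_vs_two_optima$p_value))
  cat(sprintf("  coevolution: %d pairs scored, %d flagged\n",
              x$coevo$n_pairs, x$coevo$n_flagged))
  invisible(x)
}
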