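#' Run the full comparative analysis end-to-end
#'
#' Reproduces the analysis order of the study design this package implements:
#' (1) PGLS brain-body allometry with likelihood-ratio tests of the Pagel
#' scaling parameters, refitting with any parameter that differs from 1;
#' (2) relative brain size (residuals); (3) ancestral state reconstruction of
#' brain, body and residual by the requested methods, with and without
#' fossils; (4) congruence tables (Spearman) between the with/without-fossil
#' estimates, nodes matched by their extant clade; (5) directional-trend
#' Bayes-factor tests per trait (needs fossil tips); (6) per-branch change
#' statistics and the decrease census; (7) an optional dwarfism scenario
#' grid. All tables are written as TSV next to a JSON run manifest recording
#' seeds and acceptance rates; progress goes to standard error.
#'
#' @param tree Fossil-bearing `phylo` tree.
#' @param traits Trait tibble (see [prepare_traits()]).
#' @param out_dir Output directory (created if needed).
#' @param methods ASR methods to run.
#' @param settings [mcmc_settings()] for the MCMC stages.
#' @param scenarios Optional ancestors tibble for [scenario_grid()].
#' @param descendant_brain_g,descendant_body_kg Scenario descendant masses.
#' @param drop_fossil_tips If `TRUE`, extinct tips are dropped *before* all
#'   analyses (the congruence stage then compares against the full run only
#'   if fossils exist).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Invisibly, a list with every stage's results.
#' @export
run_full_analysis <- function(tree, traits, out_dir,
                              methods = c("parsimony", "ml", "mcmc"),
                              settings = mcmc_settings(),
                              scenarios = NULL, descendant_brain_g = 380,
                              descendant_body_kg = c(16, 24, 32),
                              drop_fossil_tips = FALSE, seed = 1L) {
  stopifnot(dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE))
  methods <- match.arg(methods, several.ok = TRUE)
  log_msg <- function(...) message(sprintf(...))
  stage <- function(name, expr) {
    log_msg("[%s] running", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  check_tree_traits(tree, traits)
  has_fossils <- any(!traits$extant)
  if (drop_fossil_tips && has_fossils) {
    pruned <- drop_fossils(tree, traits)
    tree <- pruned$tree; traits <- pruned$traits
    has_fossils <- FALSE
  }
  ex <- drop_fossils(tree, traits)
  results <- list()

  # 1. PGLS + scaling tests, fitted on the full dataset (extant and fossil
  # taxa alike contribute to the allometric line)
  results$scaling_tests <- stage("pgls-scaling", {
    base <- pgls(traits, log10_brain ~ log10_body, tree)
    purrr::map_dfr(c("kappa", "lambda", "delta"), function(par) {
      free <- pgls(traits, log10_brain ~ log10_body, tree,
                   estimate_kappa = par == "kappa",
                   estimate_lambda = par == "lambda",
                   estimate_delta = par == "delta", seed = seed)
      dplyr::bind_cols(
        tibble(parameter = par, estimate = free$scaling[[par]]),
        lr_test(free, base)
      )
    })
  })
  sig <- results$scaling_tests$parameter[results$scaling_tests$p_value < 0.05]
  results$pgls <- stage("pgls-final", {
    pgls(traits, log10_brain ~ log10_body, tree,
         estimate_kappa = "kappa" %in% sig,
         estimate_lambda = "lambda" %in% sig,
         estimate_delta = "delta" %in% sig, seed = seed)
  })
  line <- as_allometry_line(results$pgls)
  readr::write_tsv(tidy(results$pgls), file.path(out_dir, "pgls_fit.tsv"))
  readr::write_tsv(results$scaling_tests, file.path(out_dir, "scaling_tests.tsv"))

  # 2. residuals
  traits <- relative_brain(traits, line)

  # 3. ASR with and without fossils
  trait_cols <- c("log10_brain", "log10_body", "residual")
  acceptance <- list()
  run_asr <- function(dat, tr, trait, method, seed_i) {
    switch(method,
      parsimony = asr_parsimony(dat, tr, trait),
      ml = asr_ml(dat, tr, trait),
      mcmc = {
        st <- settings; st$seed <- seed_i; st$sample_nodes <- TRUE
        run <- mcmc_fit(dat, tr, trait, directional = FALSE, settings = st)
        acceptance[[sprintf("%s_%d", trait, seed_i)]] <<- run$acceptance
        asr_mcmc(run)
      }
    )
  }
  results$estimates <- stage("asr", {
    grids <- tidyr::crossing(trait = trait_cols, method = methods,
                             fossils = if (has_fossils) c(TRUE, FALSE) else TRUE)
    purrr::pmap_dfr(grids, function(trait, method, fossils) {
      dat <- if (fossils) traits else ex$traits
      tr <- if (fossils) tree else ex$tree
      if (!fossils && !"residual" %in% names(dat)) dat <- relative_brain(dat, line)
      seed_i <- seed + 100L * match(trait, trait_cols) + 10L * match(method, methods) + fossils
      est <- run_asr(dat, tr, trait, method, seed_i)
      dplyr::mutate(est, trait = trait, fossils = fossils)
    })
  })
  readr::write_tsv(results$estimates, file.path(out_dir, "node_estimates.tsv"))

  # 4. congruence with vs without fossils
  if (has_fossils) {
    results$congruence <- stage("congruence", {
      map <- match_nodes_by_extant_clade(tree, ex$tree)
      purrr::pmap_dfr(tidyr::crossing(trait = trait_cols, method = methods),
        function(trait, method) {
          wf <- dplyr::filter(results$estimates, .data$trait == !!trait,
                              .data$method == !!method, .data$fossils)
          wof <- dplyr::filter(results$estimates, .data$trait == !!trait,
                               .data$method == !!method, !.data$fossils)
          a <- dplyr::inner_join(map, dplyr::select(wf, node_full = "node", "estimate"),
                                 by = "node_full")
          b <- dplyr::select(wof, node_extant = "node", b = "estimate")
          j <- dplyr::inner_join(a, b, by = "node_extant")
          dplyr::bind_cols(tibble(trait = trait, method = method),
                           congruence(j$estimate, j$b))
        })
    })
    readr::write_tsv(results$congruence, file.path(out_dir, "congruence.tsv"))
  }

  # 5. trend tests (fossil path-length variation required)
  p <- path_lengths(tree)
  if (!paths_ultrametric(p)) {
    results$trends <- stage("trend-test", {
      st <- settings; st$sample_nodes <- FALSE
      purrr::imap_dfr(setNames(trait_cols, trait_cols), function(trait, nm) {
        st$seed <- seed + 1000L + match(trait, trait_cols)
        trend_test(traits, tree, trait, settings = st)
      })
    })
    readr::write_tsv(results$trends, file.path(out_dir, "trend_tests.tsv"))
  } else {
    log_msg("[trend-test] skipped: tree is ultrametric (no path-length variation)")
  }

  # 6. branch changes and decrease census, from the preferred estimates
  results$changes <- stage("branch-changes", {
    pref_method <- if ("mcmc" %in% methods) "mcmc" else if ("ml" %in% methods) "ml" else "parsimony"
    node_vals <- function(trait_col, tip_values) {
      est <- dplyr::filter(results$estimates, .data$trait == trait_col,
                           .data$method == pref_method, .data$fossils)
      dplyr::bind_rows(
        tibble(node = match(traits$taxon, tree$tip.label), value = tip_values),
        dplyr::select(est, "node", value = "estimate")
      )
    }
    list(
      brain = branch_changes(node_vals("log10_brain", traits$log10_brain), tree),
      body = branch_changes(node_vals("log10_body", traits$log10_body), tree),
      relative = branch_changes(node_vals("residual", traits$residual), tree, raw = FALSE)
    )
  })
  all_changes <- dplyr::bind_rows(
    dplyr::mutate(results$changes$brain, trait = "brain"),
    dplyr::mutate(results$changes$body, trait = "body"),
    dplyr::mutate(results$changes$relative, trait = "relative_brain")
  )
  readr::write_tsv(all_changes, file.path(out_dir, "branch_changes.tsv"))
  results$census <- decrease_census(results$changes$brain, results$changes$body,
                                    results$changes$relative)
  readr::write_tsv(results$census$summary, file.path(out_dir, "decrease_census.tsv"))

  # 7. scenarios
  if (!is.null(scenarios)) {
    results$scenarios <- stage("scenarios", {
      env <- tryCatch(as_decrease_envelope(results$census, results$changes$relative),
                      error = function(e) NULL)
      scenario_grid(scenarios, descendant_brain_g, descendant_body_kg, line, env)
    })
    readr::write_tsv(results$scenarios, file.path(out_dir, "scenarios.tsv"))
  }

  manifest <- list(
    seed = seed, methods = methods, has_fossils = has_fossils,
    n_taxa = nrow(traits),
    mcmc = list(iterations = settings$iterations, burn_in = settings$burn_in,
                thin = settings$thin, prior = settings$prior),
    acceptance = acceptance,
    scaling_significant = sig,
    tables = list.files(out_dir, pattern = "\\.tsv$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
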