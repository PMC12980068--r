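# Umbrella pipeline: JSON-configured stages binding the generators and
# analyzers. A thin command-line wrapper around run_pipeline() ships in
# inst/scripts/twistbench.

#' Run one pipeline stage from a configuration
#'
#' Stages: `simulate` (kinds duplex, ensemble, ions, hat, rdf, cd),
#' `build-helix`, `analyze-curves`, `recover-table`, `analyze-structures`,
#' `cluster`, `kb-activity`, `map-activity`, `cd-svd`. Every stochastic
#' stage takes a `seed` and records it alongside its outputs, so a given
#' configuration is bit-reproducible. Rejected or failed inputs are counted
#' in the log rather than aborting the stage; missing inputs or unknown
#' stages abort with a nonzero status (an error).
#'
#' @param config configuration: a JSON file path or an equivalent named
#'   list. Required fields: `stage`, `out` (output file or directory);
#'   other fields are stage parameters (`seed`, `params`, input paths).
#' @return (invisibly) list of produced artifact paths; errors on any
#'   failure, producing no partial outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$stage)) stop("config must name a stage")
  stages <- c("simulate", "build-helix", "analyze-curves", "recover-table",
              "analyze-structures", "cluster", "kb-activity",
              "map-activity", "cd-svd")
  if (!config$stage %in% stages)
    stop("unknown stage: ", config$stage)
  if (is.null(config$out)) stop("config must name an output path ('out')")
  # stage inputs must exist before any output is produced
  for (f in intersect(names(config), c("curves", "pdb", "ions_pdb", "rdf",
                                       "twist", "acc", "spectra"))) {
    if (!all(file.exists(unlist(config[[f]]))))
      stop("missing input: ", paste(unlist(config[[f]]), collapse = ", "))
  }
  dir.create(dirname(config$out), showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) list() else as.list(config$params)
  log <- list(stage = config$stage, seed = seed, params = params,
              package_version = tryCatch(
                as.character(utils::packageVersion("saltwist")),
                error = function(e) NA_character_),
              rejected = 0L)
  paths <- switch(
    config$stage,
    "simulate" = .stage_simulate(config, params, seed),
    "build-helix" = {
      sp <- do.call(helix_spec, c(params, list(seed = seed)))
      write_structure(build_duplex(sp), config$out)
      config$out
    },
    "analyze-curves" = .stage_analyze_curves(config, params, log),
    "recover-table" = .stage_recover_table(config, params, seed),
    "analyze-structures" = .stage_analyze_structures(config, params),
    "cluster" = {
      s <- read_structure(config$pdb)$structure
      cutoff <- if (is.null(params$cutoff)) 0.5 else params$cutoff
      cl <- daura_cluster(s, cutoff = cutoff)
      jsonlite::write_json(list(n_clusters = length(cl$clusters),
                                largest_fraction = cl$largest_fraction,
                                representative = cl$representative,
                                cutoff = cutoff, sizes = lengths(cl$clusters)),
                           config$out, auto_unbox = TRUE, digits = NA)
      config$out
    },
    "kb-activity" = {
      rdf <- read_rdf(config$rdf, rho_c = params$rho)
      rc <- if (is.null(params$rc)) NULL else params$rc
      Gcc <- kb_integral(rdf, "cc", R_c = rc)
      Gca <- kb_integral(rdf, "ca", R_c = rc)
      acc <- activity_derivative(Gcc$G_tail, Gca$G_tail, params$rho)
      utils::write.csv(data.frame(G_cc = Gcc$G, G_ca = Gca$G,
                                  G_cc_tail = Gcc$G_tail,
                                  G_ca_tail = Gca$G_tail,
                                  rho_c = params$rho, a_cc = acc),
                       config$out, row.names = FALSE)
      config$out
    },
    "map-activity" = {
      tw <- read_schema_csv(config$twist, c("concentration", "delta_tw"))
      ac <- read_schema_csv(config$acc, "activity")
      res <- twist_vs_activity(tw, ac)
      utils::write.csv(res$table, config$out, row.names = FALSE)
      config$out
    },
    "cd-svd" = {
      set <- read_spectra(config$spectra)
      sv <- svd_decompose(set)
      band <- if (is.null(params$band)) 280 else params$band
      refc <- if (is.null(params$ref)) 0.1 else params$ref
      bt <- band_trend(set, lambda0 = band, ref_conc = refc)
      jsonlite::write_json(list(singular_values = sv$d, rank = sv$rank,
                                band_b = bt$b,
                                band_alpha_free = bt$alpha_free,
                                sign_changes = bt$sign_changes),
                           config$out, auto_unbox = TRUE, digits = NA)
      config$out
    })
  log$artifacts <- paths
  logpath <- paste0(sub("\\.(csv|json|pdb)$", "", config$out[1]), ".log.json")
  jsonlite::write_json(log, logpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, logpath))
}

.stage_simulate <- function(config, params, seed) {
  kind <- config$kind
  if (is.null(kind)) stop("simulate requires a 'kind'")
  switch(kind,
    "duplex" = {
      sp <- do.call(helix_spec, c(params, list(seed = seed)))
      d <- build_duplex(sp)
      write_structure(d, config$out)
      .write_truth(d$truth, config$out)
    },
    "ensemble" = {
      hs <- do.call(helix_spec, as.list(params$helix))
      es <- do.call(ensemble_spec,
                    c(as.list(params$ensemble), list(seed = seed)))
      e <- perturb_ensemble(build_duplex(hs), es)
      write_structure(e, config$out)
      .write_truth(list(bii_fraction_planted = e$truth$bii_fraction_planted,
                        twist_mean_planted = mean(e$truth$twist)),
                   config$out)
    },
    "ions" = {
      hs <- do.call(helix_spec, as.list(params$helix))
      is_ <- do.call(ion_spec, c(as.list(params$ions), list(seed = seed)))
      d <- build_duplex(hs)
      set <- place_ions(d, is_)
      write_structure(d, config$out, ions = set)
      .write_truth(set$truth, config$out)
    },
    "hat" = {
      sp <- do.call(hat_spec, c(params, list(seed = seed)))
      write_curve(gen_hat_curve(sp), config$out)
    },
    "rdf" = {
      sp <- do.call(rdf_spec, params)
      write_rdf(gen_rdf(sp), config$out)
    },
    "cd" = {
      sp <- do.call(cd_spec, c(params, list(seed = seed)))
      write_spectra(gen_cd_set(sp), config$out)
    },
    stop("unknown simulate kind: ", kind))
  config$out
}

.stage_analyze_curves <- function(config, params, log) {
  files <- unlist(config$curves)
  nbp <- if (is.null(params$nbp)) 20600 else params$nbp
  thr <- if (is.null(params$threshold)) 0.85 else params$threshold
  fits <- list(); meta <- list(); rejected <- 0L
  for (f in files) {
    fit <- tryCatch(fit_hat(read_curve(f, n_bp = nbp), threshold = thr),
                    error = function(e) NULL)
    if (is.null(fit)) rejected <- rejected + 1L
    else { fits[[length(fits) + 1L]] <- fit; meta[[length(meta) + 1L]] <- f }
  }
  if (!length(fits)) stop("all curves rejected")
  df <- data.frame(file = unlist(meta),
                   center_turns = vapply(fits, `[[`, 0, "center_turns"),
                   center_se = vapply(fits, `[[`, 0, "center_se"),
                   slope_neg = vapply(fits, `[[`, 0, "slope_neg"),
                   slope_pos = vapply(fits, `[[`, 0, "slope_pos"))
  utils::write.csv(df, config$out, row.names = FALSE)
  config$out
}

.stage_recover_table <- function(config, params, seed) {
  conds <- if (!is.null(config$conditions)) {
    as.data.frame(config$conditions)
  } else {
    ref <- alkali_twist_reference()
    ref[, c("salt", "concentration", "delta_tw")]
  }
  nm <- if (is.null(params$n_molecules)) 11 else params$n_molecules
  ns <- if (is.null(params$noise_sd)) 20 else params$noise_sd
  nbp <- if (is.null(params$nbp)) 20600 else params$nbp
  tab <- recover_table(conds, n_molecules = nm, noise_sd = ns, n_bp = nbp,
                       seed = seed)
  utils::write.csv(tab, config$out, row.names = FALSE)
  config$out
}

.stage_analyze_structures <- function(config, params) {
  rd <- read_structure(config$pdb)
  s <- rd$structure
  excl <- if (is.null(params$exclude_terminal)) 3 else params$exclude_terminal
  cutoff <- if (is.null(params$cutoff_ion)) 0.3 else params$cutoff_ion
  ions <- rd$ions
  if (!is.null(config$ions_pdb)) ions <- read_structure(config$ions_pdb)$ions
  nf <- n_frames(s)
  rows <- lapply(seq_len(nf), function(f) {
    msp <- mean_step_params(s, exclude_terminal = excl, frame = f)
    ax <- helix_axis_and_radius(s, exclude_terminal = excl, frame = f)
    pk <- sugar_pucker(s, frame = f)
    data.frame(frame = f, twist = msp$twist, rise = msp$rise,
               radius = ax$radius, pucker = mean(pk$P, na.rm = TRUE))
  })
  prof <- do.call(rbind, rows)
  bb <- bi_bii(s, exclude_terminal = excl)
  prof$bii_fraction <- bb$bii_fraction
  prof$n_li <- if (!is.null(ions)) count_adsorbed(s, ions, cutoff = cutoff)
  else NA_real_
  utils::write.csv(prof, config$out, row.names = FALSE)
  config$out
}
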