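# Config-driven end-to-end orchestration:
# generate/load -> annotate -> monomers -> boxes -> trees -> chip,
# with per-stage outputs and a machine-readable JSON report.

default_thresholds <- function() {
  list(identity_floor = 70, gap_min = 100L, min_monomers = 2L,
       max_divergence = 0.40, box_slack = 5L, box_max_mismatch = 0L,
       divergent_identity = 75, divergent_min_monomers = 10L,
       lag_min = 50L, lag_max = 400L, phasing_threshold = 0.3)
}

merge_defaults <- function(x, defaults) {
  for (k in names(defaults)) x[[k]] <- x[[k]] %||% defaults[[k]]
  x
}

spec_from_list <- function(s) {
  array_spec(
    sat_class = s$sat_class, n_monomers = s$n_monomers,
    divergence = s$divergence %||% 0, indel_rate = s$indel_rate %||% 0,
    intact_box_fraction = s$intact_box_fraction,
    cassettes = if (!is.null(s$cassettes)) bind_rows(map(s$cassettes, as_tibble)),
    direction_switch_at = s$direction_switch_at,
    junction_partner = if (!is.null(s$junction_partner)) spec_from_list(s$junction_partner),
    seed = s$seed %||% 1L
  )
}

drop_list_cols <- function(x) x[, !map_chr(x, function(c) class(c)[1]) %in% "list"]

#' Run the full satellite analysis pipeline from a config
#'
#' Stages (each toggleable): simulate or load reads, annotate arrays,
#' decompose monomers and profile variation, scan CENP-B boxes, build
#' per-array trees, simulate/quantify chromatin marks. Every stage writes
#' TSV/BED/bedGraph/newick outputs under `out_dir` and contributes record
#' counts to a JSON run report; identical config and seeds give identical
#' outputs. On a stage failure the report (with the failing stage named)
#' is still written before the error propagates.
#'
#' @param config Path to a YAML config or an equivalent named list. See
#'   the packaged example: `system.file("extdata", "demo_config.yaml",
#'   package = "centrosat")`.
#' @param out_dir Output directory (overrides the config entry).
#' @return The run report (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% "centrosat_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- merge_defaults(config$thresholds %||% list(), default_thresholds())
  stages_on <- merge_defaults(config$stages %||% list(),
                              list(annotate = TRUE, monomers = TRUE,
                                   boxes = TRUE, trees = TRUE, chip = TRUE))
  report <- list(seed = config$seed %||% 1L, thresholds = th,
                 stages = list(), counts = list())
  fail <- NULL
  run_stage <- function(name, fun) {
    if (!is.null(fail)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste0("error: ", conditionMessage(res))
      fail <<- name
    } else {
      report$stages[[name]] <<- "ok"
    }
    invisible(NULL)
  }

  motif <- cenpb_motif(config$motif$sequence %||% "NTTCGNNNNANNCGGGN",
                       config$motif$essential_positions %||% c(15L, 16L, 17L))
  lib <- if (is.null(config$library$source) || config$library$source == "synthetic") {
    synthetic_consensus_library(config$library$seed %||% 101L, motif = motif)
  } else {
    load_consensus_library(config$library$source, motif)
  }

  env <- new.env()
  run_stage("reads", function() {
    if (is.null(config$reads$source) || config$reads$source == "simulate") {
      specs <- map(config$reads$specs, spec_from_list)
      co <- simulate_cohort(specs, lib)
      env$cohort <- co
      env$reads <- co$reads
      write_reads_fasta(co$reads, file.path(out_dir, "reads.fasta"))
      readr::write_tsv(co$blocks, file.path(out_dir, "truth_blocks.tsv"))
      readr::write_tsv(co$monomers, file.path(out_dir, "truth_monomers.tsv"))
    } else {
      env$reads <- read_reads(config$reads$source)
    }
    report$counts$n_reads <<- length(env$reads)
  })

  if (isTRUE(stages_on$annotate)) run_stage("annotate", function() {
    ann <- annotate_cohort(env$reads, lib,
                           identity_floor = th$identity_floor,
                           gap_min = th$gap_min,
                           min_monomers = th$min_monomers)
    env$annotations <- ann
    blocks <- bind_rows(map(ann, "blocks"))
    readr::write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
    if (nrow(blocks)) {
      write_bed(mutate(blocks, name = .data$label), file.path(out_dir, "blocks.bed"))
    }
    readr::write_tsv(annotation_summary(ann), file.path(out_dir, "annotation_summary.tsv"))
    readr::write_tsv(composition_summary(ann), file.path(out_dir, "composition.tsv"))
    report$counts$n_blocks <<- nrow(blocks)
  })

  if (isTRUE(stages_on$monomers)) run_stage("monomers", function() {
    all_mono <- list()
    class_calls <- list()
    for (a in env$annotations) {
      sat_blocks <- filter(a$blocks, .data$kind == "sat")
      for (k in seq_len(nrow(sat_blocks))) {
        b <- sat_blocks[k, ]
        seq_b <- substr(env$reads[[a$read_id]], b$start + 1L, b$end)
        unit <- library_unit(lib, b$label)
        mono <- decompose_block(seq_b, unit, strand = b$strand,
                                max_divergence = th$max_divergence)
        if (nrow(mono) == 0) next
        mono <- mutate(mono, read_id = a$read_id,
                       start = .data$start + b$start, end = .data$end + b$start,
                       block_label = b$label)
        all_mono[[length(all_mono) + 1L]] <- mono
      }
      main <- sat_blocks[which.max(sat_blocks$end - sat_blocks$start), ]
      if (nrow(main) == 1) {
        cc <- assign_class(substr(env$reads[[a$read_id]], main$start + 1L, main$end),
                           lib, identity_floor = th$identity_floor,
                           divergent_identity = th$divergent_identity,
                           divergent_min_monomers = th$divergent_min_monomers,
                           max_divergence = th$max_divergence)
        class_calls[[a$read_id]] <- tibble(read_id = a$read_id, class = cc$class)
      }
    }
    env$monomers <- bind_rows(all_mono)
    readr::write_tsv(drop_list_cols(env$monomers), file.path(out_dir, "monomers.tsv"))
    if (nrow(env$monomers)) {
      write_bed(mutate(env$monomers, name = .data$sat_class),
                file.path(out_dir, "monomers.bed"))
    }
    env$class_calls <- bind_rows(class_calls)
    readr::write_tsv(env$class_calls, file.path(out_dir, "class_calls.tsv"))
    # per-class variation profiles pooled over reads
    for (cls in unique(env$monomers$sat_class)) {
      m <- filter(env$monomers, .data$sat_class == cls)
      if (nrow(m) < 2) next
      vp <- per_position_variation(m, library_unit(lib, cls))
      readr::write_tsv(vp$profile,
                       file.path(out_dir, paste0("variation_", cls, ".tsv")))
    }
    report$counts$n_monomers <<- nrow(env$monomers)
    report$counts$class_distribution <<- as.list(table(env$class_calls$class))
  })

  if (isTRUE(stages_on$boxes)) run_stage("boxes", function() {
    mi_classes <- c("MiSat120", "MiSat112", "MiSat112_64")
    mono <- filter(env$monomers, .data$sat_class %in% mi_classes)
    calls <- list()
    for (cls in unique(mono$sat_class)) {
      unit <- library_unit(lib, cls)
      for (rid in unique(mono$read_id[mono$sat_class == cls])) {
        m <- filter(mono, .data$sat_class == cls, .data$read_id == rid)
        bc <- scan_boxes(m, lib$motif, unit = unit, slack = th$box_slack,
                         max_mismatch = th$box_max_mismatch)
        calls[[length(calls) + 1L]] <- mutate(bc, array_id = rid, sat_class = cls)
      }
    }
    env$box_calls <- bind_rows(calls)
    if (nrow(env$box_calls)) {
      readr::write_tsv(drop_list_cols(env$box_calls), file.path(out_dir, "boxes.tsv"))
      readr::write_tsv(intact_density(env$box_calls),
                       file.path(out_dir, "box_density.tsv"))
      readr::write_tsv(cluster_box_variants(env$box_calls),
                       file.path(out_dir, "box_variants.tsv"))
    }
    report$counts$n_boxes <<- nrow(env$box_calls)
  })

  if (isTRUE(stages_on$trees)) run_stage("trees", function() {
    n_trees <- 0L
    for (rid in unique(env$monomers$read_id)) {
      m <- filter(env$monomers, .data$read_id == rid)
      if (nrow(m) < 3) next
      tr <- monomer_tree(m, n_max = 30L, seed = report$seed)
      ape::write.tree(tr, file.path(out_dir, paste0("tree_", rid, ".nwk")))
      n_trees <- n_trees + 1L
    }
    report$counts$n_trees <<- n_trees
  })

  chip_cfg <- config$chip
  if (isTRUE(stages_on$chip) && !is.null(chip_cfg) && !is.null(env$cohort)) {
    run_stage("chip", function() {
      refs <- array_refs(env$cohort$sat_reads, lib)
      class_map <- bind_rows(map(env$cohort$sat_reads, function(sr) {
        sat <- filter(sr$blocks, .data$kind == "sat")
        tibble(ref = sr$read_id,
               sat_class = sat$label[which.max(sat$end - sat$start)])
      }))
      depth <- chip_cfg$depth %||% 30
      # all marks and the input share one background decoy
      max_folds <- list()
      for (mk in chip_cfg$marks) {
        for (cls in names(mk$folds)) {
          max_folds[[cls]] <- max(max_folds[[cls]] %||% 1, mk$folds[[cls]])
        }
      }
      bg_len <- chip_background_length(refs, unlist(max_folds))
      in_spec <- chip_spec("input", depth = depth,
                           seed = chip_cfg$input_seed %||% (report$seed + 1000L))
      input_tr <- map_fragments(simulate_chip_fragments(refs, in_spec,
                                                        background_length = bg_len))
      enr <- list(); pha <- list()
      for (mk in chip_cfg$marks) {
        sp <- chip_spec(mk$mark, fold_by_class = unlist(mk$folds),
                        phased = isTRUE(mk$phased),
                        nucleosome_period_bp = mk$period,
                        depth = depth, seed = mk$seed %||% report$seed)
        tr <- map_fragments(simulate_chip_fragments(refs, sp,
                                                    background_length = bg_len))
        e <- fold_enrichment(tr, input_tr, class_map)
        enr[[mk$mark]] <- mutate(e, mark = mk$mark, .before = 1)
        for (rid in refs$ref) {
          ml <- class_map$sat_class[class_map$ref == rid]
          ph <- phasing(tr$tracks[[rid]], lag_min = th$lag_min,
                        lag_max = th$lag_max,
                        score_threshold = th$phasing_threshold,
                        monomer_length = library_unit(lib, ml)$monomer_length)
          pha[[length(pha) + 1L]] <- tibble(
            mark = mk$mark, ref = rid, period = ph$period, score = ph$score,
            phased = ph$phased, spacing_monomers = ph$spacing_monomers)
          write_bedgraph(tr$tracks[[rid]], rid,
                         file.path(out_dir, sprintf("coverage_%s_%s.bedgraph",
                                                    gsub("[^A-Za-z0-9]", "", mk$mark), rid)))
        }
      }
      env$enrichment <- bind_rows(enr)
      env$phasing <- bind_rows(pha)
      readr::write_tsv(env$enrichment, file.path(out_dir, "enrichment.tsv"))
      readr::write_tsv(env$phasing, file.path(out_dir, "phasing.tsv"))
      report$counts$n_marks <<- length(chip_cfg$marks)
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(fail)) {
    stopf("pipeline stage '%s' failed: %s", fail, report$stages[[fail]])
  }
  invisible(report)
}
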