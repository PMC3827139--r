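# End-to-end orchestration: one configuration object, staged execution in
# dependency order (simulate -> digest -> classify -> density -> trace ->
# map -> tree), per-stage outputs on disk and a checksummed run manifest.

PIPELINE_STAGES <- c("simulate", "digest", "classify", "density", "trace",
                     "map", "tree")

#' Pipeline configuration
#'
#' All stage parameters with their defaults: 600-bp density windows, 10-Mbp
#' regional bins, the 5/150/0.75 call filter, 25-bp large-INDEL minimum,
#' LOD 3 retention, 1000 bootstrap replicates, and IBD scanning parameters
#' (here scaled to the synthetic 1-Mbp chromosomes). Unknown keys are
#' rejected.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] for the simulate stage (its seed is forced to
#'   `seed`).
#' @param stages Stages to run, in dependency order.
#' @param window_bp Density window (bp).
#' @param bin_bp Regional bin (bp).
#' @param min_depth,max_depth,hom_af Call-filter parameters.
#' @param large_indel_min Minimum zero-depth span (bp).
#' @param lod_min LOD retention threshold.
#' @param bootstrap_replicates Bootstrap replicates for the tree stage.
#' @param ibd_threshold IBD window density threshold (variants/Kbp).
#' @param ibd_min_length,ibd_window IBD segment minimum and window (bp).
#' @param markers_per_chrom Markers sampled per chromosome for the map stage.
#' @param tag_length DG tag length (37 or 72).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = PIPELINE_STAGES,
                            window_bp = 600L,
                            bin_bp = 1e7,
                            min_depth = 5L,
                            max_depth = 150L,
                            hom_af = 0.75,
                            large_indel_min = 25L,
                            lod_min = 3,
                            bootstrap_replicates = 1000L,
                            ibd_threshold = 0.05,
                            ibd_min_length = 1e5,
                            ibd_window = 1e4,
                            markers_per_chrom = 150L,
                            tag_length = 72L) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  sim$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed), sim = sim,
    stages = stages[order(match(stages, PIPELINE_STAGES))],
    window_bp = window_bp, bin_bp = bin_bp,
    min_depth = min_depth, max_depth = max_depth, hom_af = hom_af,
    large_indel_min = large_indel_min, lod_min = lod_min,
    bootstrap_replicates = as.integer(bootstrap_replicates),
    ibd_threshold = ibd_threshold, ibd_min_length = ibd_min_length,
    ibd_window = ibd_window,
    markers_per_chrom = as.integer(markers_per_chrom),
    tag_length = as.integer(tag_length)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys override [pipeline_config()] defaults; keys under `sim`
#' override [sim_config()] defaults. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(y$sim)) {
    sim_known <- names(formals(sim_config))
    bad <- setdiff(names(y$sim), sim_known)
    if (length(bad) > 0L) {
      abort(sprintf("unknown sim key(s): %s", paste(bad, collapse = ", ")))
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

#' Default three-founder pedigree with a selection locus
#'
#' Two terminal inbred lines built by crossing and single-seed descent from
#' three race-diverse founders, with one selection locus fixed for a shared
#' founder in both terminal lines — the configuration that produces an IBD
#' region between the terminal lines.
#'
#' @param config A [sim_config()] (founder ids; locus placed on the first
#'   chromosome).
#' @return List with `pedigree` (tibble) and `selection` (tibble).
#' @export
default_pedigree <- function(config) {
  f <- names(config$founders)
  stopifnot(length(f) >= 3L)
  len <- config$chrom_length[1]
  pedigree <- tibble(
    child   = c("X_AB",  "LineA", "X_BC",  "LineB"),
    parent1 = c(f[1],    "X_AB",  f[3],    "X_BC"),
    parent2 = c(f[3],    f[1],    if (length(f) >= 5L) f[5] else f[2], f[3]),
    cross   = c("F1",    "ssd:5", "F1",    "ssd:5")
  )
  selection <- tibble(
    chrom = "chr01",
    start = as.integer(round(len * 0.70)),
    end = as.integer(round(len * 0.90)),
    founder = f[3]
  )
  list(pedigree = pedigree, selection = selection)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order over a fully synthetic
#' dataset with known truth: simulate (genome, founder panel, pedigree,
#' methylation), digest (tag prediction, recovery, methylation profile),
#' classify (call filter, consequence classification, category table),
#' density (windowed, per-gene and regional profiles; large-INDEL spans),
#' trace (pedigree origin calls, haplotype blocks, IBD), map (RIL population
#' and genetic map) and tree (founder dendrogram with bootstrap). Identical
#' configurations produce identical output checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return A `run_manifest`: tibble (`stage`, `artifact`, `path`, `md5`)
#'   with the effective config echoed to `config.yaml` and a `run.log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  manifest <- list()
  log <- c(sprintf("haplomosaic run, seed %d", config$seed),
           sprintf("stages: %s", paste(config$stages, collapse = " -> ")))
  add <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1L]] <<-
      tibble(stage = stage, artifact = artifact, path = path,
             md5 = unname(tools::md5sum(path)))
  }
  need <- function(what, from) {
    if (is.null(st[[what]])) {
      abort(sprintf("stage dependency missing: '%s' (run the '%s' stage)",
                    what, from))
    }
    st[[what]]
  }
  save_tsv <- function(stage, artifact, x) {
    p <- file.path(out_dir, paste0(artifact, ".tsv"))
    readr::write_tsv(x, p)
    add(stage, artifact, p)
  }

  for (stage in config$stages) {
    log <- c(log, sprintf("running stage: %s", stage))
    switch(stage,
      simulate = {
        st$genome <- build_reference(config$sim)
        st$landscape <- density_landscape(st$genome, config$sim)
        st$panel <- simulate_founder_variants(st$genome, st$landscape,
                                              config$sim)
        ped <- default_pedigree(config$sim)
        st$pedigree <- ped$pedigree
        st$selection <- ped$selection
        st$lines <- breed(ped$pedigree, st$panel, st$genome, config$sim,
                          selection = ped$selection)
        st$terminal <- c("LineA", "LineB")
        files <- export_dataset(st$genome, out_dir,
                                lines = st$lines[st$terminal],
                                panel = st$panel, config = config$sim)
        for (i in seq_len(nrow(files))) {
          add("simulate", files$artifact[i], files$path[i])
        }
        save_tsv("simulate", "landscape", st$landscape)
      },
      digest = {
        genome <- need("genome", "simulate")
        st$sites <- find_restriction_sites(genome)
        tags <- extract_dg_tags(genome, st$sites, config$tag_length)
        st$tags <- flag_unique_tags(tags, genome)
        meth <- simulate_methylation(genome, st$sites, config$sim)
        st$methylation <- meth
        st$recovery <- simulate_tag_recovery(
          st$tags, meth, depth_mean = config$sim$dg_depth_mean,
          min_depth = config$sim$dg_min_depth,
          seed = stage_seed(config$seed, "recovery"))
        windows <- tile_windows(genome, 5e4)
        st$meth_profile <- methylation_profile(st$recovery, windows)
        save_tsv("digest", "dg_tags", st$tags)
        save_tsv("digest", "methylation_profile",
                 as_tibble(st$meth_profile))
      },
      classify = {
        genome <- need("genome", "simulate")
        panel <- need("panel", "simulate")
        lines <- need("lines", "simulate")
        vv <- map(st$terminal, function(ln) {
          v <- line_variants(lines[[ln]], panel)
          mutate(v, comparison = paste0(ln, "/reference"))
        })
        st$variants <- bind_rows(vv)
        st$classified <- classify_variants(st$variants, genome)
        st$categories <- summarize_categories(st$classified)
        save_tsv("classify", "category_counts", st$categories)
      },
      density = {
        genome <- need("genome", "simulate")
        cls <- need("classified", "classify")
        v1 <- dplyr::filter(cls, .data$comparison ==
                              paste0(st$terminal[1], "/reference"),
                            .data$type == "SNP")
        cid <- names(genome$chrom_lengths)[1]
        region <- list(chrom = cid, start = 0L,
                       end = genome$chrom_lengths[[cid]])
        st$profile <- window_density(
          dplyr::filter(v1, .data$chrom == cid), region, config$window_bp)
        st$gene_density <- per_gene_density(v1, genome$genes)
        st$regional <- regional_density(
          dplyr::filter(v1, .data$chrom == cid), genome, region,
          bin_size = config$bin_bp)
        lines <- need("lines", "simulate")
        panel <- need("panel", "simulate")
        track <- depth_track_for_line(
          line_variants(lines[[st$terminal[1]]], panel), genome, config$sim)
        st$large_indels <- detect_large_indels(track,
                                               config$large_indel_min)
        save_tsv("density", "window_density", as_tibble(st$profile))
        save_tsv("density", "gene_density", st$gene_density)
        save_tsv("density", "regional_density", st$regional)
        save_tsv("density", "large_indels", st$large_indels)
      },
      trace = {
        panel <- need("panel", "simulate")
        lines <- need("lines", "simulate")
        pedigree <- need("pedigree", "simulate")
        sites <- polymorphic_sites(panel)
        geno_nodes <- unique(c(names(panel$founders), pedigree$child))
        st$genotypes <- genotype_lines(lines[geno_nodes], panel, sites)
        st$origins <- trace_pedigree(pedigree, st$genotypes,
                                     lines = st$terminal)
        st$blocks <- bind_rows(map(st$terminal, function(ln) {
          mutate(segment_blocks(
            dplyr::filter(st$origins, .data$line == ln)), line = ln,
            .before = 1)
        }))
        vA <- line_variants(lines[[st$terminal[1]]], panel)
        vB <- line_variants(lines[[st$terminal[2]]], panel)
        genome <- need("genome", "simulate")
        cid <- "chr01"
        st$ibd <- detect_ibd(
          pair_variant_differences(vA, vB),
          list(chrom = cid, start = 0L, end = genome$chrom_lengths[[cid]]),
          density_threshold = config$ibd_threshold,
          min_length = config$ibd_min_length, window = config$ibd_window)
        save_tsv("trace", "haplotype_blocks", st$blocks)
        save_tsv("trace", "ibd_segments", st$ibd)
      },
      map = {
        panel <- need("panel", "simulate")
        lines <- need("lines", "simulate")
        genome <- need("genome", "simulate")
        pop <- generate_ril_population(
          as_inbred(lines[[st$terminal[1]]]),
          as_inbred(lines[[st$terminal[2]]]),
          n = config$sim$ril_n, generations = config$sim$ril_generations,
          genome = genome, config = config$sim)
        markers <- with_seed(stage_seed(config$seed, "markers"), {
          bind_rows(map(names(genome$chrom_lengths), function(cid) {
            tibble(chrom = cid,
                   pos = sort(sample.int(genome$chrom_lengths[[cid]],
                                         config$markers_per_chrom)))
          }))
        })
        st$ril_genotypes <- ril_genotypes(pop, markers)
        st$map <- assemble_map(st$ril_genotypes, lod_min = config$lod_min)
        save_tsv("map", "ril_genotypes", st$ril_genotypes)
        save_tsv("map", "genetic_map", st$map$markers)
        save_tsv("map", "map_density", map_density(st$map, 1e5))
      },
      tree = {
        panel <- need("panel", "simulate")
        mat <- marker_character_matrix(panel)
        st$tree <- bootstrap_support(
          mat, replicates = config$bootstrap_replicates,
          seed = stage_seed(config$seed, "bootstrap"))
        p <- file.path(out_dir, "founders.nwk")
        writeLines(to_newick(st$tree), p)
        add("tree", "founder_tree", p)
      }
    )
  }
  cfgp <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), cfgp)
  manifest <- bind_rows(manifest)
  logp <- file.path(out_dir, "run.log")
  writeLines(c(log, sprintf("artifacts: %d", nrow(manifest))), logp)
  structure(manifest, class = c("run_manifest", class(manifest)),
            state = as.list(st), config = config)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$founders <- as.list(out$sim$founders)
  out$sim$p_methylated <- as.list(out$sim$p_methylated)
  out
}

#' Tile a genome's chromosomes with fixed-size windows
#'
#' @param genome An `annotated_genome`.
#' @param window Window size (bp).
#' @return Tibble (`chrom`, `start`, `end`).
#' @export
tile_windows <- function(genome, window = 5e4) {
  bind_rows(imap(as.list(genome$chrom_lengths), function(len, cid) {
    starts <- seq(0L, len - 1L, by = window)
    tibble(chrom = cid, start = as.integer(starts),
           end = as.integer(pmin(starts + window, len)))
  }))
}

#' Symmetric variant differences between two lines
#'
#' Sites carried by exactly one line, or by both with different alleles —
#' the pairwise polymorphism set used for density profiling and IBD
#' scanning.
#'
#' @param v1,v2 Variant tibbles from [line_variants()].
#' @return Tibble (`chrom`, `pos`, `type`).
#' @export
pair_variant_differences <- function(v1, v2) {
  m <- dplyr::full_join(
    select(v1, "chrom", "pos", "type", alt1 = "alt"),
    select(v2, "chrom", "pos", type2 = "type", alt2 = "alt"),
    by = c("chrom", "pos")
  )
  m <- dplyr::filter(m, is.na(.data$alt1) | is.na(.data$alt2) |
                       .data$alt1 != .data$alt2)
  mutate(m, type = dplyr::coalesce(.data$type, .data$type2)) |>
    select("chrom", "pos", "type") |>
    arrange(.data$chrom, .data$pos)
}
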