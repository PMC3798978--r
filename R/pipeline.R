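#' Default run configuration
#'
#' @return a nested list with every pipeline parameter at its packaged
#'   default, suitable for writing out as YAML and editing.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    fis_bend = 65,
    contact_cutoff = 6,
    enhancer = list(total_bp = 65L, site_block_bp = 21L, core_bp = 15L,
                    center_separation_bp = 47L, site1_center = 10L),
    substrate = list(loop99_bp = 99L, invertible_bp = 1000L,
                     plasmid_bp = 3000L, plectoneme_turns = 4L),
    state = "cleaved",
    rotations = 2L
  )
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

#' Validate a run configuration
#'
#' Schema and invariant checks without running anything.
#'
#' @param config path to a YAML configuration, or a configuration list.
#' @return character vector of diagnostics (empty when the configuration is
#'   valid).
#' @export
validate_config <- function(config) {
  cfg <- .load_config(config)
  diag <- character(0)
  say <- function(...) diag <<- c(diag, paste0(...))
  for (f in c("seed", "enhancer", "substrate", "state")) {
    if (is.null(cfg[[f]])) say("missing section or field: ", f)
  }
  if (!is.null(cfg$state) &&
      !cfg$state %in% c("cleaved", "pre_cleaved", "dimer_docked", "all")) {
    say("unknown state: ", cfg$state)
  }
  if (!is.null(cfg$fis_bend) && (cfg$fis_bend < 0 || cfg$fis_bend >= 180)) {
    say("fis_bend out of range [0, 180)")
  }
  e <- cfg$enhancer
  if (!is.null(e)) {
    need <- c("total_bp", "core_bp", "center_separation_bp", "site1_center")
    miss <- setdiff(need, names(e))
    if (length(miss)) say("enhancer section missing: ", paste(miss, collapse = ", "))
    if (all(need %in% names(e))) {
      half <- (e$core_bp - 1) %/% 2
      s2 <- e$site1_center + e$center_separation_bp
      if (s2 + half > e$total_bp || e$site1_center - half < 1) {
        say("center_separation_bp inconsistent with site indices: ",
            "core sites do not fit in total_bp")
      }
    }
  }
  s <- cfg$substrate
  if (!is.null(s)) {
    for (f in c("loop99_bp", "invertible_bp", "plasmid_bp")) {
      if (is.null(s[[f]])) say("substrate section missing: ", f)
      else if (s[[f]] <= 0) say("negative or zero loop length: ", f)
    }
    if (!is.null(s$loop99_bp) && !is.null(s$invertible_bp) &&
        s$loop99_bp > 0 && s$invertible_bp > 0 &&
        s$loop99_bp + 65 + 26 >= s$invertible_bp) {
      say("loop99_bp too long for the invertible segment")
    }
    if (!is.null(s$invertible_bp) && !is.null(s$plasmid_bp) &&
        s$invertible_bp + 26 >= s$plasmid_bp) {
      say("invertible segment exceeds plasmid size")
    }
  }
  if (!is.null(cfg$rotations) && (cfg$rotations < 0 || cfg$rotations > 6)) {
    say("rotations must be between 0 and 6")
  }
  diag
}

.spec_from_config <- function(cfg) {
  e <- cfg$enhancer
  layout <- enhancer_layout(total_bp = e$total_bp,
                            site_block_bp = e$site_block_bp %||% 21L,
                            core_bp = e$core_bp,
                            center_separation_bp = e$center_separation_bp,
                            site1_center = e$site1_center)
  fixture_spec(seed = cfg$seed, fis_bend = cfg$fis_bend %||% 65,
               layout = layout,
               loop99_bp = cfg$substrate$loop99_bp,
               invertible_bp = cfg$substrate$invertible_bp,
               plasmid_bp = cfg$substrate$plasmid_bp,
               contact_cutoff = cfg$contact_cutoff %||% 6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten an assembly into one multi-chain atom set
#'
#' DNA duplexes are represented by their pseudo-phosphate backbones
#' (enhancer chains E/F, hix1 G/H, hix2 I/J), the Fis dimers by chains
#' A/B and C/D, and the Hin subunits by chains K (hix1L), L (hix1R),
#' M (hix2L), N (hix2R).
#'
#' @param a an `assembly`.
#' @return an [atom_set()].
#' @export
assembly_to_atom_set <- function(a) {
  rows <- list()
  add <- function(chain, resno, resname, atom, xyz, element) {
    rows[[length(rows) + 1L]] <<- list(chain = chain, resno = resno,
                                       resname = resname, atom = atom,
                                       xyz = xyz, element = element)
  }
  dna <- function(model, ch1, ch2) {
    n <- nrow(model$backbone$top)
    add(rep(ch1, n), seq_len(n), "DN", "P", model$backbone$top, "P")
    add(rep(ch2, n), seq_len(n), "DN", "P", model$backbone$bottom, "P")
  }
  dna(a$enhancer, "E", "F"); dna(a$hix1, "G", "H"); dna(a$hix2, "I", "J")
  prot <- function(set, map) {
    rec <- set$records
    add(map[rec$chain], rec$resno, rec$resname, rec$atom, set$xyz, rec$element)
  }
  prot(a$fis1, c(A = "A", B = "B"))
  prot(a$fis2, c(A = "C", B = "D"))
  hin_ch <- c(hix1L = "K", hix1R = "L", hix2L = "M", hix2R = "N")
  for (hs in names(a$hin)) prot(a$hin[[hs]], stats::setNames(hin_ch[[hs]], "H"))
  chain <- unlist(lapply(rows, `[[`, "chain"))
  atom_set(chain = chain,
           resno = unlist(lapply(rows, `[[`, "resno")),
           resname = unlist(lapply(rows, `[[`, "resname")),
           atom = unlist(lapply(rows, `[[`, "atom")),
           xyz = do.call(rbind, lapply(rows, `[[`, "xyz")),
           element = unlist(lapply(rows, `[[`, "element")))
}

#' Run the full modeling pipeline
#'
#' Builds the synthetic fixtures from the configuration, assembles the
#' requested invertasome state(s), scores the packaged crosslink set,
#' predicts the FeBABE footprints, runs the DNA-topology simulation, and
#' writes models (PDB), curves, footprints (BED) and a machine-readable
#' report to the output directory.  Identical configurations give identical
#' reports.
#'
#' @param config YAML path or configuration list (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @return the run report (a list), invisibly; the same content is written
#'   to `report.yaml` in `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("ivs_run_")) {
  cfg <- .load_config(config)
  diag <- validate_config(cfg)
  if (length(diag)) stop("invalid configuration:\n  ", paste(diag, collapse = "\n  "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- .spec_from_config(cfg)
  states <- if (identical(cfg$state, "all")) {
    c("dimer_docked", "pre_cleaved", "cleaved")
  } else cfg$state

  report <- list(config = cfg, states = list())
  cleaved_assembly <- NULL
  for (st in states) {
    comp <- make_toy_components(spec, st)
    a <- assemble_invertasome(assembly_config(comp,
                                              contact_cutoff = spec$contact_cutoff))
    write_pdb(assembly_to_atom_set(a), file.path(outdir, paste0("assembly_", st, ".pdb")))
    xl <- crosslink_report(a)
    utils::write.table(xl, file.path(outdir, paste0("crosslinks_", st, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$states[[st]] <- list(
      crosslinks_satisfied = sum(xl$satisfied),
      crosslinks_total = nrow(xl))
    if (st == "cleaved") cleaved_assembly <- a
  }
  if (!is.null(cleaved_assembly)) {
    for (teth in c("Hin:hix1L:54", "Hin:hix2R:54", "Fis1:A:98", "Fis2:B:98")) {
      fp <- predict_febabe_footprint(cleaved_assembly, teth)
      fn <- paste0("footprint_", gsub(":", "_", teth), ".bed")
      write_footprint_bed(fp, file.path(outdir, fn))
    }
  }

  s <- make_substrate_geometry(spec)
  write_curve(s$curve, file.path(outdir, "substrate_curve.txt"))
  nodes <- count_nodes(s$curve, c("hix1", "hix2"), "enhancer")
  rot <- list()
  nmax <- cfg$rotations %||% 2L
  for (n in seq_len(max(1L, nmax))) {
    p <- simulate_rotation(s, n)
    rot[[as.character(n)]] <- list(
      orientation = p$orientation,
      delta_linking = delta_linking(s, p),
      knot_determinant = knot_determinant(p$curve))
    if (n == 1L) write_curve(p$curve, file.path(outdir, "product_n1_curve.txt"))
  }
  report$topology <- list(
    branch_nodes = nrow(nodes),
    branch_node_signs = nodes$sign,
    substrate_writhe = writhe(s$curve),
    rotations = rot)
  report$seed <- cfg$seed
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  invisible(report)
}
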