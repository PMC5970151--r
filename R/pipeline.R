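# Five-stage orchestration with the three clinician checkpoints:
#   stage 1  input model and curves
#   stage 2  basic covering-surface generation   -> checkpoint 1 (sections)
#   stage 3  division and thickness generation   -> checkpoint 2 (surface/report)
#   stage 4  lattice-structure creation          -> checkpoint 3 (pattern SVGs)
#   stage 5  rounded-edge and screw-seat generation

#' Pipeline configuration
#'
#' Every rule constant of the design system in one place; all overridable and
#' logged into the output metadata for provenance.
#'
#' @param offset_mm swelling offset applied to the limb (2)
#' @param section_spacing_mm gradual-station spacing (15; practice 10-20)
#' @param n_u circumferential samples per section (96; divisible by 2 and 3)
#' @param reference_area_cm2 2-vs-3-part threshold (260)
#' @param area_domain_cm2 thickness remap domain (c(150, 600))
#' @param thickness_range_mm thickness remap range (c(2.8, 4.0))
#' @param lattice_cu,lattice_cv mm of panel per lattice division (20, 28)
#' @param margin_M,margin_N frame and truss margins in mm (8, 1.6)
#' @param edge_trim rim tube trim domain (c(0.01, 0.99))
#' @param tube_extra_mm tube diameter excess over thickness (1.5)
#' @param seat_positions parametric seat positions (c(0.1, 0.9))
#' @param seat_midpoint_threshold_mm midpoint-seat rule (180, strict)
#' @param repair_points section-repair interpolation points (16)
#' @param bridge_side_offset_mm dual-section corridor half-width (5)
#' @param splint_type "auto" (area rule), "wrist_2part", or "forearm"
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(offset_mm = 2, section_spacing_mm = 15, n_u = 96,
                            reference_area_cm2 = 260,
                            area_domain_cm2 = c(150, 600),
                            thickness_range_mm = c(2.8, 4.0),
                            lattice_cu = 20, lattice_cv = 28,
                            margin_M = 8, margin_N = 1.6,
                            edge_trim = c(0.01, 0.99), tube_extra_mm = 1.5,
                            seat_positions = c(0.1, 0.9),
                            seat_midpoint_threshold_mm = 180,
                            repair_points = 16, bridge_side_offset_mm = 5,
                            splint_type = c("auto", "wrist_2part", "forearm")) {
  splint_type <- match.arg(splint_type)
  stopifnot(offset_mm >= 0, section_spacing_mm > 0, n_u >= 12,
            reference_area_cm2 > 0, all(area_domain_cm2 > 0),
            all(thickness_range_mm > 0), margin_M > 0, margin_N > 0,
            edge_trim[1] >= 0, edge_trim[2] <= 1, edge_trim[1] < edge_trim[2],
            tube_extra_mm > 0, all(seat_positions > 0 & seat_positions < 1),
            seat_midpoint_threshold_mm > 0, repair_points >= 4,
            bridge_side_offset_mm > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from TOML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#' @param path TOML file
#' @return pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- RcppTOML::parseTOML(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Run the full splint-design pipeline
#'
#' Executes the five stages. In `interactive` mode the run pauses at the three
#' checkpoints, dumps preview artifacts and asks the `approve` gate (default:
#' terminal prompt) before continuing; in `batch` mode checkpoints are dumped
#' (when `out_dir` is set) and auto-approved. Stage timings are reported.
#'
#' @param mesh limb trimesh (placement convention: +X axis, on the XY plane)
#' @param curveA,curveB [input_curve] objects (A distal, B proximal)
#' @param config [pipeline_config()]
#' @param mode "batch" or "interactive"
#' @param out_dir if set, checkpoint dumps, STL parts and metadata are written
#' @param approve function(checkpoint_id, state) -> logical; gate for
#'   interactive mode
#' @return list with `parts` (splint_part list), `surface`, `area_cm2`,
#'   `thickness_mm`, `n_parts`, `stage_reports`, `checkpoint_files`
#' @export
run_pipeline <- function(mesh, curveA, curveB, config = pipeline_config(),
                         mode = c("batch", "interactive"), out_dir = NULL,
                         approve = NULL) {
  mode <- match.arg(mode)
  if (is.null(approve)) {
    approve <- if (mode == "interactive" && interactive()) {
      function(id, state) {
        ans <- readline(sprintf("checkpoint %d: continue? [y/N] ", id))
        tolower(substr(ans, 1, 1)) == "y"
      }
    } else {
      function(id, state) TRUE
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  reports <- list()
  ckfiles <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage_report <- function(id, t0, summary, warnings = character()) {
    structure(list(stage = id, elapsed_s = tic() - t0, summary = summary,
                   warnings = warnings), class = "stage_report")
  }

  # stage 1: input model and curves -----------------------------------------
  t0 <- tic()
  if (!inherits(mesh, "trimesh")) stop("stage 1: mesh must be a trimesh")
  if (!inherits(curveA, "input_curve") || !inherits(curveB, "input_curve")) {
    stop("stage 1: curves must be input_curve objects")
  }
  placement <- validate_placement(mesh)
  reports$stage1 <- stage_report(1, t0, sprintf(
    "mesh %d faces, %d hole(s), axis off by %.1f deg",
    nrow(mesh$faces), placement$boundary_loops, placement$axis_alignment_deg))

  # stage 2: basic covering surface -----------------------------------------
  t0 <- tic()
  offset <- offset_limb(mesh, config$offset_mm)
  stations <- plan_stations(curveA, curveB, config$section_spacing_mm)
  sections <- lapply(stations, function(st) {
    secs <- cut_section(offset, st)
    resolve_station_sections(secs, repair_points = config$repair_points,
                             side_offset_mm = config$bridge_side_offset_mm)
  })
  ss <- build_section_set(sections, n_u = config$n_u)
  guides <- extract_guides(ss)
  surface <- skin_surface(ss, guides)
  area <- surface_area(surface)
  reports$stage2 <- stage_report(2, t0, sprintf(
    "%d stations, %d repaired, %d merged, area %.1f cm^2",
    length(stations), sum(ss$repaired), sum(ss$merged), area))
  state <- list(config = config, placement = placement, stations = stations,
                sections = sections, section_set = ss, guides = guides,
                surface = surface, area_cm2 = area)
  ckfiles$cp1 <- checkpoint_dump(state, 1, out_dir)
  if (!approve(1, state)) stop("stopped at checkpoint 1 (sections)")

  # stage 3: division and thickness -----------------------------------------
  t0 <- tic()
  n_parts <- decide_parts(area, config$reference_area_cm2, config$splint_type)
  thickness <- thickness_from_area(area, config$area_domain_cm2,
                                   config$thickness_range_mm)
  anchor <- seam_anchor_from_guides(ss)
  plan <- division_plan(n_parts, seam_anchor_u = anchor,
                        reference_area_cm2 = config$reference_area_cm2)
  subs <- divide_surface(surface, plan)
  shells <- lapply(subs, make_solid_shell, thickness_mm = thickness)
  reports$stage3 <- stage_report(3, t0, sprintf(
    "%d parts, thickness %.2f mm, part areas %s cm^2",
    n_parts, thickness,
    paste(sprintf("%.1f", vapply(subs, sub_surface_area, numeric(1))),
          collapse = "/")))
  state$n_parts <- n_parts; state$thickness_mm <- thickness
  state$plan <- plan; state$shells <- shells
  ckfiles$cp2 <- checkpoint_dump(state, 2, out_dir)
  if (!approve(2, state)) stop("stopped at checkpoint 2 (division/thickness)")

  # stage 4: lattice ---------------------------------------------------------
  t0 <- tic()
  patterns <- lapply(shells, function(sh) {
    pd <- panel_dimensions(sh)
    diamond_pattern(pd[1], pd[2], M = config$margin_M, N = config$margin_N,
                    c_u = config$lattice_cu, c_v = config$lattice_cv)
  })
  shells <- Map(engrave_shell, shells, patterns)
  reports$stage4 <- stage_report(4, t0, sprintf(
    "divisions %s, %s cells",
    paste(vapply(patterns, function(p) paste(p$divisions, collapse = "x"), ""),
          collapse = ", "),
    paste(vapply(shells, function(s) s$hole_count, integer(1)), collapse = "/")))
  state$patterns <- patterns; state$shells <- shells
  ckfiles$cp3 <- checkpoint_dump(state, 3, out_dir)
  if (!approve(3, state)) stop("stopped at checkpoint 3 (lattice)")

  # stage 5: rounded edges and screw seats -----------------------------------
  t0 <- tic()
  parts <- lapply(shells, function(sh) {
    assemble_features(sh, seat_positions = config$seat_positions,
                      midpoint_threshold_mm = config$seat_midpoint_threshold_mm,
                      tube_trim = config$edge_trim,
                      tube_extra_mm = config$tube_extra_mm)
  })
  reports$stage5 <- stage_report(5, t0, sprintf(
    "%d parts with %s seats",
    length(parts),
    paste(vapply(parts, function(p) length(p$seats), integer(1)), collapse = "/")))

  if (!is.null(out_dir)) {
    export_parts(parts, out_dir, state)
  }
  list(parts = parts, surface = surface, area_cm2 = area,
       thickness_mm = thickness, n_parts = n_parts, shells = shells,
       patterns = patterns, stage_reports = reports, checkpoint_files = ckfiles)
}

# Lateral seam anchor: u fraction of the y-max extreme on the middle section,
# so a two-part split separates dorsal/volar halves.
#' @keywords internal
seam_anchor_from_guides <- function(ss) {
  g <- ss$grid
  mid <- ceiling(dim(g)[1] / 2)
  (which.max(g[mid, , 2]) - 1) / dim(g)[2]
}

#' Dump a checkpoint's preview artifacts
#'
#' Checkpoint 1 writes the section polylines (with repair/merge bookkeeping)
#' as JSON; checkpoint 2 the covering surface as OBJ plus an area/thickness/
#' part-count report; checkpoint 3 the per-part lattice previews as SVG.
#'
#' @param state pipeline state list (see [run_pipeline()])
#' @param checkpoint_id 1, 2 or 3
#' @param out_dir target directory or NULL (no-op)
#' @return character vector of files written
#' @export
checkpoint_dump <- function(state, checkpoint_id, out_dir) {
  if (is.null(out_dir)) return(character(0))
  if (checkpoint_id == 1) {
    f <- file.path(out_dir, "checkpoint1_sections.json")
    secs <- lapply(state$sections, function(s) list(
      station = s$station_index, closed = s$closed,
      repaired = s$repaired, merged = s$merged,
      points = round(s$points, 4)))
    jsonlite::write_json(secs, f, auto_unbox = TRUE, digits = NA)
    return(f)
  }
  if (checkpoint_id == 2) {
    f1 <- file.path(out_dir, "checkpoint2_surface.obj")
    write_surface_obj(state$surface, f1)
    f2 <- file.path(out_dir, "checkpoint2_report.json")
    jsonlite::write_json(list(
      area_cm2 = state$area_cm2, n_parts = state$n_parts,
      thickness_mm = state$thickness_mm,
      v_edge_lengths_mm = lapply(state$shells, `[[`, "v_edge_lengths_mm")),
      f2, auto_unbox = TRUE, digits = NA)
    return(c(f1, f2))
  }
  if (checkpoint_id == 3) {
    vapply(seq_along(state$patterns), function(i) {
      f <- file.path(out_dir, sprintf("checkpoint3_pattern_part%d.svg", i))
      write_pattern_svg(state$patterns[[i]], f)
    }, character(1))
  }
}

# STL export plus assembly metadata.
#' @keywords internal
export_parts <- function(parts, out_dir, state) {
  n <- length(parts)
  for (i in seq_len(n)) {
    write_mesh(parts[[i]]$mesh,
               file.path(out_dir, sprintf("part_%d_of_%d.stl", i, n)))
  }
  meta <- list(
    n_parts = n,
    area_cm2 = state$area_cm2,
    thickness_mm = state$thickness_mm,
    config = unclass(state$config),
    seats = lapply(parts, function(p) lapply(p$seats, function(fr)
      list(origin = round(fr$origin, 4), axis = round(fr$axis, 6),
           t = fr$t, edge = fr$edge))))
  jsonlite::write_json(meta, file.path(out_dir, "assembly_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Summarize a pipeline output directory
#'
#' Reads the assembly metadata written by [run_pipeline()] and prints the key
#' numbers (area, thickness, parts, seats).
#' @param out_dir directory previously passed to run_pipeline
#' @return the metadata list, invisibly
#' @export
splint_report <- function(out_dir) {
  f <- file.path(out_dir, "assembly_metadata.json")
  if (!file.exists(f)) stop("no assembly_metadata.json in ", out_dir)
  meta <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  cat(sprintf("splint set: %d parts, area %.1f cm^2, thickness %.2f mm\n",
              meta$n_parts, meta$area_cm2, meta$thickness_mm))
  for (i in seq_along(meta$seats)) {
    cat(sprintf("  part %d: %d screw seats\n", i, length(meta$seats[[i]])))
  }
  invisible(meta)
}
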