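## synthetic sections, mapping-score distributions and alignment
## fixtures with known ground truth: every pipeline stage is testable
## offline, with no downloads

#' Synthetic-section configuration
#'
#' Defaults emulate a small MERSCOPE-like field of view: ~10 um somata
#' (radius mean 5 um), 7 z-planes at 1.5 um spacing, ~200 transcripts
#' per soma, ~1.5% blank codewords, ~3% planted doublets and a low
#' extracellular noise rate. Divisions carry mutually exclusive marker
#' blocks so incongruent-gene logic is exercisable.
#'
#' @param n_cells,n_genes,n_divisions dataset size.
#' @param radius_mean,radius_sd cell radius, um.
#' @param z_planes,z_spacing_um imaging planes.
#' @param transcripts_per_cell mean (Poisson) transcripts per cell.
#' @param noise_rate_um2 extracellular transcripts per um^2.
#' @param blank_rate fraction of blank codewords added per cell.
#' @param doublet_rate fraction of cells planted as close pairs
#'   (< 5 um apart).
#' @param low_quality_frac fraction of cells planted low-quality (very
#'   few transcripts and genes).
#' @param extent_um square section side, um.
#' @param n_blank_codes number of distinct "Blank-*" codewords.
#' @param seed mandatory RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 120L, n_genes = 48L, n_divisions = 3L,
                         radius_mean = 5, radius_sd = 0.8,
                         z_planes = 7L, z_spacing_um = 1.5,
                         transcripts_per_cell = 200,
                         noise_rate_um2 = 0.02, blank_rate = 0.008,
                         doublet_rate = 0.03, low_quality_frac = 0,
                         extent_um = 300, n_blank_codes = 10L, seed = 1L) {
  stopifnot(blank_rate >= 0, blank_rate <= 1, doublet_rate >= 0,
            doublet_rate <= 1, low_quality_frac >= 0, low_quality_frac < 1,
            is_number(seed))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic section with ground truth
#'
#' Cells are 3D Gaussian blobs with division-specific gene profiles:
#' each division owns an exclusive marker block (80% of a cell's
#' transcripts) plus a shared housekeeping block. Doublets are planted
#' as cell pairs with centers < 5 um apart; low-quality plants emit only
#' a handful of transcripts; blanks are sprinkled per cell at
#' `blank_rate`; extracellular noise is uniform with random genes. A
#' DAPI-like volume image of Gaussian bumps at nuclei is rendered at
#' `voxel_um` resolution. Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config].
#' @param voxel_um voxel size of the DAPI/density grid (default 2 um).
#' @return list(`spots` [spot_table], `dapi` [volume_image], `truth`
#'   list(`cells` data.frame(center/radius/division/quality),
#'   `doublet_pairs`, `low_quality`, `profiles`, `markers`)).
#' @export
generate_section <- function(cfg = synth_config(), voxel_um = 2) {
  with_seed(cfg$seed, {
    ext <- cfg$extent_um
    margin <- 3 * cfg$radius_mean
    n <- cfg$n_cells
    ## non-doublet cells keep >= 2 * radius_mean * 2 separation
    min_sep <- 2.2 * cfg$radius_mean
    centers <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(centers) < n) {
      cand <- runif(2, margin, ext - margin)
      if (!nrow(centers) ||
          min(sqrt(colSums((t(centers) - cand)^2))) > min_sep)
        centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 200L * n)
        stop_merscape("extent too small to place ", n, " cells",
                      class = "merscape_placement_error")
    }
    division <- rep_len(paste0("D", seq_len(cfg$n_divisions)), n)
    radius <- pmax(1.5, rnorm(n, cfg$radius_mean, cfg$radius_sd))

    ## doublet plants: partner cell < 5 um from its host
    n_dbl <- round(cfg$doublet_rate * n)
    doublet_pairs <- NULL
    if (n_dbl > 0) {
      hosts <- sample.int(n, n_dbl)
      for (h in hosts) {
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 2, 4.9)
        centers <- rbind(centers, centers[h, ] + d * c(cos(ang), sin(ang)))
        division <- c(division,
                      sample(setdiff(unique(division), division[h]), 1L))
        radius <- c(radius, pmax(1.5, rnorm(1, cfg$radius_mean, cfg$radius_sd)))
      }
      doublet_pairs <- cbind(host = hosts, partner = n + seq_len(n_dbl))
    }
    n_all <- nrow(centers)

    ## low-quality plants: almost-empty cells
    n_lq <- round(cfg$low_quality_frac * n)
    low_quality <- if (n_lq > 0) sample.int(n, n_lq) else integer(0)

    ## gene panel: per-division exclusive marker blocks + shared genes
    per_div <- floor(cfg$n_genes * 0.75 / cfg$n_divisions)
    divs <- paste0("D", seq_len(cfg$n_divisions))
    markers <- list()
    gidx <- 0L
    for (dv in divs) {
      markers[[dv]] <- sprintf("G%03d", gidx + seq_len(per_div))
      gidx <- gidx + per_div
    }
    shared <- sprintf("G%03d", seq(gidx + 1L, cfg$n_genes))
    genes_all <- c(unlist(markers, use.names = FALSE), shared)
    profiles <- lapply(divs, function(dv) {
      p <- setNames(rep(0, length(genes_all)), genes_all)
      p[markers[[dv]]] <- 0.8 / length(markers[[dv]])
      p[shared] <- 0.2 / length(shared)
      p
    })
    names(profiles) <- divs

    ## emit transcripts
    z_max <- cfg$z_planes * cfg$z_spacing_um
    glist <- list(); xs <- list(); ys <- list(); zs <- list()
    tx_cell <- list()
    for (i in seq_len(n_all)) {
      lam <- if (i %in% low_quality) 8 else cfg$transcripts_per_cell
      m <- rpois(1, lam)
      if (i %in% low_quality) {
        ## low-quality plants draw from very few genes
        gdraw <- sample(markers[[division[i]]][1:3], m, replace = TRUE)
      } else {
        gdraw <- sample(genes_all, m, replace = TRUE,
                        prob = profiles[[division[i]]])
      }
      sdv <- radius[i] / 2
      xs[[i]] <- rnorm(m, centers[i, 1L], sdv)
      ys[[i]] <- rnorm(m, centers[i, 2L], sdv)
      zs[[i]] <- runif(m, 0, z_max)
      glist[[i]] <- gdraw
      tx_cell[[i]] <- rep(i, m)
      ## blanks per cell
      nb <- rpois(1, cfg$blank_rate * m)
      if (nb > 0) {
        glist[[i]] <- c(glist[[i]],
                        paste0("Blank-", sample.int(cfg$n_blank_codes, nb,
                                                    replace = TRUE)))
        xs[[i]] <- c(xs[[i]], rnorm(nb, centers[i, 1L], sdv))
        ys[[i]] <- c(ys[[i]], rnorm(nb, centers[i, 2L], sdv))
        zs[[i]] <- c(zs[[i]], runif(nb, 0, z_max))
        tx_cell[[i]] <- c(tx_cell[[i]], rep(i, nb))
      }
    }
    ## extracellular noise (random genes + occasional blanks)
    n_noise <- rpois(1, cfg$noise_rate_um2 * ext^2)
    if (n_noise > 0) {
      gn <- sample(genes_all, n_noise, replace = TRUE)
      bl <- runif(n_noise) < cfg$blank_rate
      gn[bl] <- paste0("Blank-", sample.int(cfg$n_blank_codes, sum(bl),
                                            replace = TRUE))
      glist <- c(glist, list(gn))
      xs <- c(xs, list(runif(n_noise, 0, ext)))
      ys <- c(ys, list(runif(n_noise, 0, ext)))
      zs <- c(zs, list(runif(n_noise, 0, z_max)))
      tx_cell <- c(tx_cell, list(rep(NA_integer_, n_noise)))
    }
    spots <- spot_table(gene = unlist(glist), x = unlist(xs),
                        y = unlist(ys), z = unlist(zs), section_id = "S1")
    truth_cell <- unlist(tx_cell)

    ## DAPI-like bumps at nuclei
    dims <- c(cfg$z_planes, ceiling(ext / voxel_um), ceiling(ext / voxel_um))
    dapi <- array(0, dims)
    gz <- (seq_len(dims[1L]) - 0.5) * cfg$z_spacing_um
    gy <- (seq_len(dims[2L]) - 0.5) * voxel_um
    gx <- (seq_len(dims[3L]) - 0.5) * voxel_um
    for (i in seq_len(n_all)) {
      wy <- exp(-(gy - centers[i, 2L])^2 / (2 * (radius[i] / 2)^2))
      wx <- exp(-(gx - centers[i, 1L])^2 / (2 * (radius[i] / 2)^2))
      bump <- outer(wy, wx)
      for (zp in seq_len(dims[1L])) dapi[zp, , ] <- dapi[zp, , ] + bump
    }
    dapi <- volume_image(dapi, origin = c(0, 0, 0),
                         voxel_size = c(voxel_um, voxel_um, cfg$z_spacing_um))

    list(spots = spots,
         dapi = dapi,
         truth = list(
           cells = data.frame(cell = seq_len(n_all),
                              x = centers[, 1L], y = centers[, 2L],
                              radius = radius, division = division,
                              low_quality = seq_len(n_all) %in% low_quality),
           spot_cell = truth_cell,
           doublet_pairs = doublet_pairs,
           low_quality = low_quality,
           profiles = profiles,
           markers = markers))
  })
}

#' Generate per-cell mapping scores with planted contaminants
#'
#' Per supertype the main mode is `Normal(mu_s, 0.03^2)` with `mu_s`
#' drawn uniformly in `[0.45, 0.8]`; contaminants (fraction
#' `contaminant_frac`) sit in a displaced mode `Normal(mu_s - 0.25,
#' 0.03^2)`. Ground-truth contaminant flags are returned.
#'
#' @param n_supertypes,n_cells_per dataset size.
#' @param contaminant_frac in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return data.frame(`cell_id`, `supertype`, `avg_correlation`,
#'   `is_contaminant`).
#' @export
generate_mapping_scores <- function(n_supertypes = 5L, n_cells_per = 400L,
                                    contaminant_frac = 0.1, seed = 1L) {
  stopifnot(contaminant_frac >= 0, contaminant_frac < 0.5)
  with_seed(seed, {
    rows <- lapply(seq_len(n_supertypes), function(s) {
      mu <- runif(1, 0.45, 0.8)
      n_cont <- round(contaminant_frac * n_cells_per)
      n_main <- n_cells_per - n_cont
      sc <- c(rnorm(n_main, mu, 0.03), rnorm(n_cont, mu - 0.25, 0.03))
      data.frame(cell_id = sprintf("st%02d-c%04d", s, seq_len(n_cells_per)),
                 supertype = sprintf("ST%02d", s),
                 avg_correlation = pmin(1, pmax(-1, sc)),
                 is_contaminant = c(rep(FALSE, n_main), rep(TRUE, n_cont)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a QuickNII/VisuAlign alignment fixture with known truth
#'
#' The planted warp is affine (amplitude-scaled rotation/shear +
#' translation), so its piecewise-linear landmark interpolation is exact
#' everywhere and round-trip tests can compare against analytically
#' warped coordinates. Landmarks sit on a regular grid; anchors map the
#' normalized section onto an atlas plane; the annotation volume is a
#' labelled block grid at 25 um voxels.
#'
#' @param n_sections number of sections.
#' @param n_landmarks approximate landmarks per section (gridded).
#' @param warp_amplitude affine perturbation scale (0 = identity warp).
#' @param seed RNG seed.
#' @param dir output directory for the JSON files.
#' @param width,height image dimensions in pixels.
#' @return list(`quicknii_json`, `visualign_json` file paths,
#'   `volume` annotation volume, `truth` per-section list(`warp`
#'   function, `anchor`)).
#' @export
generate_alignment_fixture <- function(n_sections = 2L, n_landmarks = 9L,
                                       warp_amplitude = 0.05, seed = 1L,
                                       dir = tempdir(),
                                       width = 400, height = 300) {
  stopifnot(n_landmarks >= 3)
  with_seed(seed, {
    g <- max(2L, ceiling(sqrt(n_landmarks)))
    gx <- seq(0, width, length.out = g)
    gy <- seq(0, height, length.out = g)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    slices_q <- list(); slices_v <- list(); truth <- list()
    for (s in seq_len(n_sections)) {
      nm <- sprintf("section_%02d.png", s)
      ## affine warp: identity + small rotation/shear/translation
      th <- warp_amplitude * rnorm(1)
      A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L) +
        warp_amplitude * matrix(rnorm(4, sd = 0.2), 2L)
      b <- warp_amplitude * rnorm(2, sd = 10)
      make_warp <- function(A, b) {
        force(A); force(b)
        if (warp_amplitude == 0) function(p) as.matrix(p)
        else function(p) as.matrix(p) %*% t(A) +
               matrix(b, nrow(p), 2L, byrow = TRUE)
      }
      warp_fun <- make_warp(A, b)
      tgt <- warp_fun(grid)
      ## anchor: section s at depth s*100 um, 10 um/px in-plane
      o <- c(0, 0, s * 100)
      u <- c(width * 10, 0, 0)
      v <- c(0, height * 10, 0)
      slices_q[[s]] <- list(filename = nm, anchoring = c(o, u, v),
                            width = width, height = height)
      slices_v[[s]] <- list(filename = nm, width = width, height = height,
                            markers = lapply(seq_len(nrow(grid)), function(i)
                              c(grid[i, ], tgt[i, ])))
      truth[[nm]] <- list(warp = warp_fun,
                          anchor = list(o = o, u = u, v = v))
    }
    qpath <- file.path(dir, "quicknii.json")
    vpath <- file.path(dir, "visualign.json")
    jsonlite::write_json(list(slices = slices_q), qpath, auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(list(slices = slices_v), vpath, auto_unbox = TRUE,
                         digits = NA)
    ## annotation volume: 25 um voxels, labelled blocks along x
    dims <- c(ceiling(width * 10 / 25), ceiling(height * 10 / 25),
              ceiling((n_sections + 1) * 100 / 25))
    labels <- array(0L, dims)
    n_blocks <- 4L
    bw <- ceiling(dims[1L] / n_blocks)
    for (b in seq_len(n_blocks)) {
      xi <- ((b - 1L) * bw + 1L):min(b * bw, dims[1L])
      labels[xi, , ] <- b
    }
    vol <- list(labels = labels, voxel_um = 25,
                region_names = setNames(paste0("region_", 0:n_blocks),
                                        as.character(0:n_blocks)))
    list(quicknii_json = qpath, visualign_json = vpath, volume = vol,
         truth = truth)
  })
}
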