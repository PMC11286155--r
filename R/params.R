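#' @importFrom stats approxfun median quantile rlnorm runif setNames rnorm
#' @importFrom utils modifyList packageVersion write.csv head tail
NULL

# Reference surrogate dimensions (mm) at 48 months of age.  These are the
# calibrated defaults: stylized, desk-scale stand-ins for a 4-year-old
# cranium, chosen once so that the lever geometry (bite points vs. TMJ) and
# the arch/fascia load geometry reproduce the published force ratios.  All
# other ages are produced by the growth scaling below.
.skull_ref <- list(
  ax = 40, ay = 50, az = 36,     # calvarial semi-axes (x: half-breadth,
                                 # y: half-length, z: half-height)
  shell_t  = 4,                  # calvarial shell thickness
  pl_hw    = 41,                 # facial plate half-width
  pl_t     = 5,                  # facial plate (antero-posterior) thickness
  pl_y0    = 43,                 # facial plate posterior face
  pl_zlo   = -42, pl_zhi = -6,   # facial plate vertical extent (face height)
  pal_hw   = 30,                 # palate half-width
  pal_y0   = 16,                 # palate posterior edge
  pal_t    = 5,                  # palate slab thickness
  pal_ztop = -35,                # palate top surface
  pil_x0   = 10, pil_x1 = 18,    # pterygoid pillar lateral extent
  pil_y0   = 16, pil_y1 = 23,    # pillar antero-posterior extent
  pil_z1   = -26,                # pillar top (reaches the skull base shell)
  arch_x   = 40,                 # zygomatic arch axis, lateral offset
  arch_r   = 2.2,                # arch tube radius (slender strut)
  arch_z   = -20,                # arch axis height
  arch_y0  = -8, arch_y1 = 44,   # arch span (posterior -> anterior)
  root_x0  = 31,                 # arch root block (posterior attachment)
  root_y0  = -12, root_y1 = -2,
  coronal_y  = 12,               # coronal suture plane
  lambdoid_y = -28,              # lambdoid suture plane
  base_cut_z = -12.6,            # below this the shell is skull base (-.35 az)
  base_joint_z = -18,            # synchondrosis ring height (-.5 az)
  fontanelle_r = 7,              # anterior fontanelle patch radius
  suture_w = 2                   # suture band width at 3 months
)

# Muscle / fascia attachment layout, 48-month reference, left side (x > 0).
# Stations along the zygomatic arch are fractions of the arch span measured
# from the posterior end.  Insertion points are virtual markers (the
# surrogate has no mandible); only the origin->insertion direction is used.
.attach_ref <- list(
  tem_o_y = c(30, 18, 4),  tem_o_z = c(6, 9, 6),    # temporalis origins (on wall)
  tem_i   = c(31, 33, -38),                         # coronoid process marker
  mas_fr  = c(0.9, 0.7, 0.2),                       # masseter stations on arch
  mas_i   = c(37, 18, -52),                         # ramus/gonial marker
  pt_o    = c(14, 19, -38),                         # medial pterygoid origin
  pt_i    = c(24, 0, -56),                          # gonion, medial aspect
  fas_fr  = c(0.65, 0.50, 0.35),                    # fascia stations on arch
  fas_z   = -2                                      # fascia marks height on wall
)

# Bite points, TMJ and facial probes, 48-month reference, left side / midline.
.sites_ref <- list(
  incisor = c(3, 47.5, -41),
  molar   = c(27, 35, -39),
  tmj     = list(c(40, -4, -23.2), c(40, -8, -23.2)),
  probes  = list(
    lateral_inferior_forehead = c(30, 41, -8),
    nasion                    = c(0, 46, -9),
    alare                     = c(8, 46, -30),
    frontal_process_maxilla   = c(16, 45, -14),
    lateral_process_maxilla   = c(34, 43, -32),
    inferior_orbital_roof     = c(18, 43, -12),
    frontal_process_zygoma    = c(36, 41, -14),
    central_zygoma            = c(40, 36, -20),
    central_palate            = c(0, 30, -36)
  )
)

.bone_labels  <- c("frontal", "parietal", "occipital", "facial",
                   "zygomatic_arch_L", "zygomatic_arch_R", "skull_base")
.joint_labels <- c("metopic", "coronal", "sagittal", "lambdoid",
                   "facial_suture", "base_joint", "anterior_fontanelle")
.suture_host  <- c(metopic = "frontal", coronal = "parietal",
                   sagittal = "parietal", lambdoid = "occipital",
                   facial_suture = "facial", base_joint = "skull_base",
                   anterior_fontanelle = "parietal")

#' Parameters of the synthetic skull surrogate
#'
#' Builds the full parameter set describing the stylized infant-cranium
#' surrogate at a given age: an ellipsoidal calvarial shell, a facial plate
#' with palate and pterygoid pillars, tubular zygomatic arches, suture bands,
#' and all attachment/bite/probe sites.  Linear dimensions grow monotonically
#' with age; facial height grows faster than width (controlled by
#' `face_exponent`), mimicking the proportional change from a wide, short
#' infant face to a taller child face.
#'
#' @param age_months age in months, in \[3, 48\].
#' @param pitch voxel pitch (mm) used to discretize the surrogate.  Must be
#'   at most half the shell thickness so the calvarial shell is resolved by
#'   at least two voxels.
#' @param size_scale global scale factor applied to all reference lengths.
#' @param shell_thickness calvarial shell thickness in mm (does not scale
#'   with age: infant cranial vault thickness changes little compared with
#'   overall head size at this stylization level).
#' @param suture_width suture band width in mm at 3 months; scales with age.
#'   Bands are always at least one voxel layer wide once discretized.
#' @param growth_s3 ratio of a linear skull dimension at 3 months to the same
#'   dimension at 48 months (default 0.78, head-circumference-like growth).
#' @param face_exponent exponent applied to the growth factor for facial
#'   vertical dimensions (> 1 means the face grows faster in height than the
#'   skull does overall).
#' @param arch_clearance extra lateral stand-off (mm) added to the zygomatic
#'   arch axis; useful for coarse meshes where the default arch-to-wall gap
#'   would fall below one voxel.
#' @param seed integer seed recorded with the mesh (generation is
#'   deterministic; the seed is kept for provenance).
#' @return an object of class `skull_params`: a named list of absolute
#'   dimensions (mm) for the requested age, plus attachment, bite, TMJ and
#'   probe site coordinates.  The effective zygomatic arch length (mm) is in
#'   `$arch_length`.
#' @export
#' @examples
#' p <- skull_params(48)
#' p$ax; p$arch_length
skull_params <- function(age_months, pitch = 2, size_scale = 1,
                         shell_thickness = 4, suture_width = 2,
                         growth_s3 = 0.78, face_exponent = 1.35,
                         arch_clearance = 0, seed = 1L) {
  if (!is.numeric(age_months) || length(age_months) != 1L ||
      is.na(age_months) || age_months < 3 || age_months > 48)
    stop("age_months must be a single value in [3, 48]", call. = FALSE)
  if (pitch <= 0 || size_scale <= 0 || shell_thickness <= 0)
    stop("pitch, size_scale and shell_thickness must be positive",
         call. = FALSE)
  if (pitch > shell_thickness / 2)
    stop("resolution error: voxel pitch ", pitch,
         " mm is too coarse to resolve the ", shell_thickness,
         " mm calvarial shell (need pitch <= thickness/2)", call. = FALSE)

  g  <- growth_s3 + (1 - growth_s3) * (age_months - 3) / 45
  gf <- g^face_exponent
  sc  <- g  * size_scale   # general linear scale
  scf <- gf * size_scale   # facial-height scale

  r <- .skull_ref
  # mesh-robustness floors for the thinner secondary structures
  floor2 <- 1.25 * pitch
  p <- list(
    age_months = age_months, pitch = pitch, size_scale = size_scale,
    seed = as.integer(seed), growth = g, growth_face = gf,
    ax = r$ax * sc, ay = r$ay * sc, az = r$az * sc,
    shell_t = shell_thickness * size_scale,
    pl_hw = r$pl_hw * sc, pl_t = max(r$pl_t * sc, floor2),
    pl_y0 = r$pl_y0 * sc, pl_zlo = r$pl_zlo * scf, pl_zhi = r$pl_zhi * sc,
    pal_hw = r$pal_hw * sc, pal_y0 = r$pal_y0 * sc,
    pal_t = max(r$pal_t * sc, floor2), pal_ztop = r$pal_ztop * scf,
    pil_x0 = r$pil_x0 * sc, pil_x1 = max(r$pil_x1 * sc,
                                         r$pil_x0 * sc + floor2),
    pil_y0 = r$pil_y0 * sc, pil_y1 = max(r$pil_y1 * sc,
                                         r$pil_y0 * sc + floor2),
    pil_z1 = r$pil_z1 * sc,
    arch_x = r$arch_x * sc + arch_clearance,
    arch_r = max(r$arch_r * sc, 1.05 * pitch),
    arch_z = r$arch_z * sc, arch_y0 = r$arch_y0 * sc, arch_y1 = r$arch_y1 * sc,
    root_x0 = r$root_x0 * sc + 0.5 * arch_clearance,
    root_y0 = r$root_y0 * sc, root_y1 = r$root_y1 * sc,
    coronal_y = r$coronal_y * sc, lambdoid_y = r$lambdoid_y * sc,
    base_cut_z = r$base_cut_z * sc, base_joint_z = r$base_joint_z * sc,
    fontanelle_r = r$fontanelle_r * sc,
    suture_w = suture_width * (0.8 + 0.2 * g / growth_s3) * size_scale
  )
  p$shell_t <- max(p$shell_t, 2 * pitch)  # keep the invariant under scaling
  a <- .attach_ref
  p$attach <- list(
    tem_o = cbind(NA_real_, a$tem_o_y * sc, a$tem_o_z * sc),  # x from shell
    tem_i = a$tem_i * c(sc, sc, scf),
    mas_fr = a$mas_fr, mas_i = a$mas_i * c(sc, sc, scf),
    pt_o = a$pt_o * c(sc, sc, scf), pt_i = a$pt_i * c(sc, sc, scf),
    fas_fr = a$fas_fr, fas_z = a$fas_z * sc
  )
  s <- .sites_ref
  scale3 <- function(v) v * c(sc, sc, scf)
  p$sites <- list(
    incisor = scale3(s$incisor), molar = scale3(s$molar),
    tmj = lapply(s$tmj, function(v) v * sc),
    probes = lapply(s$probes, scale3)
  )
  p$arch_length <- p$arch_y1 - p$arch_y0
  # sanity: suture band narrower than smallest plate dimension
  if (p$suture_w >= min(p$pl_t, p$shell_t, 2 * p$arch_r))
    stop("suture band width must be smaller than the thinnest plate",
         call. = FALSE)
  class(p) <- "skull_params"
  p
}

#' @export
print.skull_params <- function(x, ...) {
  cat("<skull_params>  age", x$age_months, "months, pitch", x$pitch, "mm\n")
  cat(sprintf("  calvaria %.1f x %.1f x %.1f mm (semi-axes), shell %.1f mm\n",
              x$ax, x$ay, x$az, x$shell_t))
  cat(sprintf("  face height %.1f mm, arch length %.1f mm\n",
              x$pl_zhi - x$pl_zlo, x$arch_length))
  invisible(x)
}

#' Suture patency schedule
#'
#' Returns the set of cranial joints still patent (modelled as compliant
#' suture material) at a given age.  The default schedule closes joints in
#' three steps: facial and skull-base joints first, then the calvarial
#' sutures, with the anterior fontanelle persisting longest; from 24 months
#' on the model is fully ossified.  The active set is monotone decreasing in
#' age, so a later age never re-opens a joint.
#'
#' @param age_months age in months.
#' @param schedule optional named list of breakpoints: a list of
#'   `list(min_age, labels)` entries; the entry with the largest `min_age`
#'   not exceeding `age_months` is used.
#' @return character vector of active suture labels (possibly empty).
#' @export
suture_schedule <- function(age_months, schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- list(
      list(min_age = 0,
           labels = c("metopic", "coronal", "sagittal", "lambdoid",
                      "anterior_fontanelle", "facial_suture", "base_joint")),
      list(min_age = 6,
           labels = c("metopic", "coronal", "sagittal", "lambdoid",
                      "anterior_fontanelle")),
      list(min_age = 12, labels = "anterior_fontanelle"),
      list(min_age = 24, labels = character(0))
    )
  }
  ages <- vapply(schedule, function(e) e$min_age, numeric(1))
  labs <- lapply(schedule, function(e) as.character(e$labels))
  # monotonicity: later sets must be subsets of earlier ones
  o <- order(ages)
  for (i in seq_along(o)[-1])
    if (!all(labs[[o[i]]] %in% labs[[o[i - 1]]]))
      stop("suture schedule is not monotone: active set at age ",
           ages[o[i]], " is not a subset of the previous set", call. = FALSE)
  sel <- max(which(ages[o] <= age_months))
  labs[[o[sel]]]
}

# map suture labels back to their host bone when closed
.relabel_closed <- function(label, active) {
  closed <- setdiff(.joint_labels, active)
  idx <- label %in% closed
  label[idx] <- .suture_host[label[idx]]
  label
}
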