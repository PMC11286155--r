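#' Age-dependent material model for cranial bone and joints
#'
#' Cranial bone and cranial joints (sutures, fontanelles, synchondroses) are
#' isotropic linear elastic.  At 3 months of age the elastic moduli are
#' 421 MPa (bone) and 30 MPa (joint); bone stiffens by 125 MPa per month up
#' to 48 months and joint tissue by 100 MPa per month up to 12 months, after
#' which the joint modulus is frozen.  Poisson ratios are 0.22 (bone) and
#' 0.30 (joint) at all ages.
#'
#' @param E_bone0,E_joint0 baseline moduli (MPa) at 3 months.
#' @param bone_rate,joint_rate stiffening rates (MPa per month).
#' @param joint_freeze_age age (months) after which the joint modulus stops
#'   increasing.
#' @param nu_bone,nu_joint Poisson ratios.
#' @return an object of class `age_material_model`.
#' @export
age_material_model <- function(E_bone0 = 421, bone_rate = 125,
                               E_joint0 = 30, joint_rate = 100,
                               joint_freeze_age = 12,
                               nu_bone = 0.22, nu_joint = 0.30) {
  stopifnot(E_bone0 > 0, E_joint0 > 0, bone_rate >= 0, joint_rate >= 0,
            nu_bone > -1, nu_bone < 0.5, nu_joint > -1, nu_joint < 0.5)
  structure(list(E_bone0 = E_bone0, bone_rate = bone_rate,
                 E_joint0 = E_joint0, joint_rate = joint_rate,
                 joint_freeze_age = joint_freeze_age,
                 nu_bone = nu_bone, nu_joint = nu_joint),
            class = "age_material_model")
}

#' Evaluate the material model at an age
#'
#' @param age_months age in months, in \[3, 48\].
#' @param model an [age_material_model()].
#' @return named list with `E_bone`, `nu_bone`, `E_joint`, `nu_joint`
#'   (moduli in MPa).
#' @export
#' @examples
#' material_at_age(3)   # bone 421 MPa, joint 30 MPa
#' material_at_age(48)  # joint modulus frozen after month 12
material_at_age <- function(age_months, model = age_material_model()) {
  if (!is.numeric(age_months) || length(age_months) != 1L ||
      is.na(age_months) || age_months < 3 || age_months > 48)
    stop("age_months must be a single value in [3, 48]", call. = FALSE)
  list(E_bone = model$E_bone0 + model$bone_rate * (age_months - 3),
       nu_bone = model$nu_bone,
       E_joint = model$E_joint0 +
         model$joint_rate * (min(age_months, model$joint_freeze_age) - 3),
       nu_joint = model$nu_joint)
}

# per-element (E, nu) from region labels
.element_materials <- function(label, age_months, model = age_material_model()) {
  m <- material_at_age(age_months, model)
  joint <- label %in% .joint_labels
  list(E = ifelse(joint, m$E_joint, m$E_bone),
       nu = ifelse(joint, m$nu_joint, m$nu_bone))
}
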