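#' Surface area of a spherical spine head
#'
#' Spine heads are treated as spheres, so the membrane area follows from
#' the volume as \eqn{A = (36\pi)^{1/3} V^{2/3}}. The average spine of
#' 0.08 um^3 has an area of 0.898 um^2.
#'
#' @param V spine volume (um^3), scalar or vector, all > 0
#' @return surface area (um^2)
#' @examples
#' areaFromVolume(0.08)
#' @export
areaFromVolume <- function(V) {
  if (any(V <= 0)) stop("volume must be > 0")
  (36 * pi)^(1 / 3) * V^(2 / 3)
}

#' @rdname areaFromVolume
#' @param A surface area (um^2), all > 0
#' @export
volumeFromArea <- function(A) {
  if (any(A <= 0)) stop("area must be > 0")
  A^(3 / 2) / (6 * sqrt(pi))
}

#' Endocytosis rate closing the mobile-pool steady state
#'
#' With the influx (exocytosis + lateral diffusion) and the target
#' steady state fixed, the endocytosis rate follows analytically from
#' the fixed-point condition of the mobile pool:
#' \deqn{k_{endo} = [A^0_{spine}(k^0_{exo} S^0_{exo} + k_{in}) -
#'   k_{out} U^*] / U^*.}
#'
#' @param p a [TraffickingParams-class] object
#' @return endocytosis rate (um^2/s)
#' @seealso [deriveKUB0()]
#' @export
deriveKEndo <- function(p) {
  if (p@UStar <= 0) stop("UStar must be > 0")
  k <- (p@ASpine0 * (p@kExo0 * p@SExo0 + p@kIn) - p@kOut * p@UStar) / p@UStar
  if (k < 0)
    stop("inconsistent parameters: influx too small for the target U* ",
         "(derived kEndo would be negative)")
  k
}

#' Basal binding rate closing the bound-pool steady state
#'
#' The binding rate at the PSD that makes (U*, B*) a fixed point of the
#' bound-receptor equation:
#' \deqn{k^0_{UB} = A^0_{spine} k_{BU} B^* / [(P - B^*) U^*].}
#'
#' @param p a [TraffickingParams-class] object
#' @return binding rate (um^2/(# s))
#' @export
deriveKUB0 <- function(p) {
  if (p@UStar <= 0) stop("UStar must be > 0")
  if (p@P <= p@BStar) stop("need P > BStar")
  p@ASpine0 * p@kBU * p@BStar / ((p@P - p@BStar) * p@UStar)
}

#' Construct the basal trafficking parameter set
#'
#' Defaults reproduce the average hippocampal spine used throughout the
#' model hierarchy: a 0.08 um^3 spine with 70 PSD slots holding
#' U* = 10 mobile and B* = 20 bound receptors (28.5% occupancy).
#' `kIn` and `kOut` are built from a single per-receptor exchange rate
#' `kInPrime` (#/s leaving per receptor) as `kIn = kInPrime * UStar` and
#' `kOut = kInPrime * ASpine0`, which keeps diffusion balanced when the
#' steady state is changed. `kEndo` and `kUB0` are derived from the
#' fixed-point closure unless given explicitly.
#'
#' @param kExo0 basal exocytosis event rate (events/s)
#' @param SExo0 receptors per exocytosis event (#)
#' @param kBU unbinding rate (1/s)
#' @param P number of PSD slots
#' @param UStar,BStar steady-state mobile/bound receptor numbers
#' @param VSpine0 basal spine volume (um^3)
#' @param kInPrime per-receptor diffusive exchange rate (1/s)
#' @param kIn,kOut,kEndo,kUB0 optional explicit values overriding the
#'   balanced/derived defaults
#' @param kUB0Coop basal binding rate of the cooperative model; usually
#'   left `NA` and filled in from a calibration via [coopKUB0()]
#' @return a validated [TraffickingParams-class] object
#' @examples
#' p <- traffickingParams()
#' p$kEndo   # 0.0021 um^2/s (2 s.f.)
#' p$kUB0    # 0.0036 um^2/(# s) (2 s.f.)
#' @export
traffickingParams <- function(kExo0 = 0.0018, SExo0 = 13, kBU = 0.1,
                              P = 70, UStar = 10, BStar = 20,
                              VSpine0 = 0.08, kInPrime = 0.02,
                              kIn = NULL, kOut = NULL,
                              kEndo = NULL, kUB0 = NULL,
                              kUB0Coop = NA_real_) {
  ASpine0 <- areaFromVolume(VSpine0)
  if (is.null(kIn)) kIn <- kInPrime * UStar
  if (is.null(kOut)) kOut <- kInPrime * ASpine0
  obj <- new("TraffickingParams", kExo0 = kExo0, SExo0 = SExo0,
             kEndo = 0, kIn = kIn, kOut = kOut, kBU = kBU, kUB0 = 0,
             kUB0Coop = as.numeric(kUB0Coop), P = P, UStar = UStar,
             BStar = BStar, VSpine0 = VSpine0, ASpine0 = ASpine0)
  obj@kEndo <- if (is.null(kEndo)) deriveKEndo(obj) else kEndo
  obj@kUB0 <- if (is.null(kUB0)) deriveKUB0(obj) else kUB0
  validObject(obj)
  obj
}

#' Scale the PSD slot number with the spine surface area
#'
#' The PSD grows linearly with the spine membrane:
#' \eqn{P = P^{basal} A_{spine} / A^{basal}_{spine}}. The continuous
#' value is used by the mean-field model; round it for lattice use.
#'
#' @param ASpine spine surface area (um^2)
#' @param PBasal slot number of the reference spine (70)
#' @param ABasal area of the reference spine (0.898 um^2)
#' @return continuous slot count
#' @export
scaleSlots <- function(ASpine, PBasal = 70,
                       ABasal = areaFromVolume(0.08)) {
  if (any(c(ASpine, PBasal, ABasal) <= 0)) stop("all arguments must be > 0")
  PBasal * ASpine / ABasal
}
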