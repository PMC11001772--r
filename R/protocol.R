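#' Patterning-protocol configuration
#'
#' Records the wet-lab protocol quantities: stock and working concentrations
#' of the fibrin gel components, the cell suspension, the chamber geometry,
#' the drive parameters (54 Hz, 1.2 g — metadata selecting the standing
#' mode experimentally; the simulation is parameterized directly by the mode
#' indices), and the confocal scan geometry.
#'
#' @param fibrinogenStock,fibrinogenWorking mg/mL.
#' @param thrombinStock,thrombinWorking IU/mL.
#' @param mixRatio gel:cell-suspension volume mixing ratio (1 = 1:1).
#' @param cellSuspensionDensity cells/mL before mixing.
#' @param cellRatio HUVEC:pericyte ratio.
#' @param roundDiameter,squareSide chamber dimensions, mm.
#' @param frequencyHz,accelerationG drive parameters.
#' @param scanAreaRound,scanAreaSquare overview scan areas, mm^2.
#' @param zDepthUm Z-stack depth, um.
#' @param sliceThicknessUm Z-slice thickness, um.
#' @return A validated list of class `ProtocolConfig`.
#' @export
protocolConfig <- function(fibrinogenStock = 15, fibrinogenWorking = 5,
                           thrombinStock = 100, thrombinWorking = 0.5,
                           mixRatio = 1, cellSuspensionDensity = 3e6,
                           cellRatio = 10, roundDiameter = 21,
                           squareSide = 15, frequencyHz = 54,
                           accelerationG = 1.2, scanAreaRound = 543,
                           scanAreaSquare = 350, zDepthUm = 350,
                           sliceThicknessUm = 30) {
  cfg <- list(fibrinogenStock = fibrinogenStock,
              fibrinogenWorking = fibrinogenWorking,
              thrombinStock = thrombinStock,
              thrombinWorking = thrombinWorking, mixRatio = mixRatio,
              cellSuspensionDensity = cellSuspensionDensity,
              cellRatio = cellRatio, roundDiameter = roundDiameter,
              squareSide = squareSide, frequencyHz = frequencyHz,
              accelerationG = accelerationG, scanAreaRound = scanAreaRound,
              scanAreaSquare = scanAreaSquare, zDepthUm = zDepthUm,
              sliceThicknessUm = sliceThicknessUm)
  if (any(vapply(cfg, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all protocol quantities must be positive numbers")
  class(cfg) <- c("ProtocolConfig", "list")
  cfg
}

#' Protocol and scan-volume arithmetic
#'
#' Derived wet-lab quantities: 1:1 mixing of the fibrinogen and
#' thrombin-cell working solutions halves each concentration (5 mg/mL
#' fibrinogen -> 2.5 mg/mL; 0.5 IU/mL thrombin -> 0.25 IU/mL; 3e6 cells/mL
#' -> 1.5e6 cells/mL for the default 1:1 ratio), and the imaged volume is
#' scan area x Z-depth with unit conversion (350 mm^2 x 350 um = 122.5 mm^3;
#' 543 mm^2 x 350 um = 190.05 mm^3).
#'
#' @param config a [protocolConfig].
#' @return Named list: `finalFibrinogen` (mg/mL), `finalThrombin` (IU/mL),
#'   `finalCellDensity` (cells/mL), `scanVolumeRound`, `scanVolumeSquare`
#'   (mm^3), `nSlices`.
#' @examples
#' protocolArithmetic(protocolConfig())
#' @export
protocolArithmetic <- function(config = protocolConfig()) {
  if (!inherits(config, "ProtocolConfig"))
    config <- do.call(protocolConfig, config)
  gelFrac <- config$mixRatio / (1 + config$mixRatio)       # fibrinogen part
  cellFrac <- 1 / (1 + config$mixRatio)                    # cell-suspension part
  list(finalFibrinogen = config$fibrinogenWorking * gelFrac,
       finalThrombin = config$thrombinWorking * cellFrac,
       finalCellDensity = config$cellSuspensionDensity * cellFrac,
       scanVolumeRound = config$scanAreaRound * config$zDepthUm / 1000,
       scanVolumeSquare = config$scanAreaSquare * config$zDepthUm / 1000,
       nSlices = config$zDepthUm / config$sliceThicknessUm)
}
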