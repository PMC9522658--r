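# kymodec

Singular value decomposition of intravital line-scan fluorescence waveforms
from kidney proximal-tubule cells.

## The problem

The proximal tubule (PT) reabsorbs filtered plasma proteins and degrades
them in its endo-lysosomal system: early endosomes (EE) just under the
apical membrane, large apical vacuoles (LAV) and lysosomes in the mid-cell
region. Intravital microscopy can record line scans across PT cells over
time, but the compartments overlap in space, so their individual kinetics
cannot be read off the raw traces. Because the fluorescence at each
position and time is, to good approximation, a *linear combination* of the
compartment signals, the waveform can be disentangled model-free.

Each tubule's data form a matrix **A** (m position bins × n time points;
positions normalised to [0, 1] with 0 = apical). Its singular value
decomposition

    A = U S Vᵀ

yields paired base vectors: column i of **U** is a spatial profile, column
i of **V** a kinetic time course, and the singular value Sᵢ their weight.
Components are kept while (a) their energy share Sᵢ²/ΣS² is at least 1%
and (b) the lag-1 autocorrelations of both the U and V columns are at
least 0.5 (noise vectors decorrelate at lag 1; structured ones do not);
scanning stops at the first rejected component. Setting the remaining
singular values to zero gives a denoised reconstruction, and the
singular-value-weighted readouts Sᵢ·Vᵢ quantify each process over time.

A second readout of fluorescence physics makes degradation visible in
real time: a protein carrying n fluorophores self-quenches, emitting
n·q^(n−1) relative units intact but n after proteolysis, so degradation
multiplies brightness by the unquenching gain q^(1−n).

The package provides, as testable units:

* a forward simulator of line-scan waveforms, whole-tubule time series and
  axial uptake profiles, with compartment kinetics, unquenching physics,
  noise, and perturbation scenarios (cathepsin inhibition, labeling
  density, uptake defects);
* line-scan preprocessing: position rescaling/orientation, pooled mean
  binning, waveform assembly, artifact QC flags;
* the decomposition with rank selection, denoising, component readouts and
  component-to-compartment matching;
* kinetic metrics: onset and delay detection, ROI ordering, uptake length,
  intracellular dispersion and its axial correlation;
* in silico tryptic digestion (Keil rule) with monoisotopic [M+H]+ masses
  and small/large fragment routing.

## Worked example

```r
library(kymodec)

sc  <- defaultScenario("healthy-S1")   # 3 compartments, 50 ROIs, 60 frames
w   <- simulateWaveform(sc)            # 100 bins x 60 time points
res <- selectRank(decomposeWaveform(w))
res
#> SVDResult: 100 position bins x 60 time points
#>   selected rank: 3
#>  component singularValue energyShare    acU    acV retained
#>          1        41.210     0.74100  0.980  0.740     TRUE
#>          2        22.260     0.21600  0.990  0.930     TRUE
#>          3         7.053     0.02170  0.970  0.940     TRUE
#>          4         1.620     0.00115 -0.079 -0.042    FALSE
#>          5         1.525     0.00101  0.028  0.025    FALSE
#>   ... 55 more components
```

Three base vectors carry 97.9% of the energy and are retained; component 4
already looks like noise (energy 0.1%, autocorrelations near zero). The
retained spatial shapes correspond to the broad mid-cell LAV signal, the
sub-apical EE peak and the narrow mid-cell lysosome signal
(`componentReadouts(res)`, `matchComponents(res, ...)`).

Whole-tubule kinetics from the compartmental model:

```r
ctrl <- simulateTubuleSeries(sc)
inh  <- simulateTubuleSeries(defaultScenario("e64-inhibited"))
deg  <- TubuleTimeSeries("S1_degradation", seriesTimes(ctrl$S1),
  seriesIntensities(ctrl$S1) - seriesIntensities(inh$S1))
onsetTime(deg, 0.5)            # 10.59 min: degradation starts ~10 min post injection
delayBetween(deg, ctrl$S2)     # 3.89 min: S2 signal lags S1 degradation
```

Peptide tools:

```r
digestTable(c(fragment = "VYVEELKPTPEGDLEILLQK", demo = "ALKGWR"))
#>   protein             sequence length   mh_mono mh_rounded size_class
#>  fragment VYVEELKPTPEGDLEILLQK     20 2313.2588       2313      large
#>      demo                  ALK      3  331.2340        331      small
#>      demo                  GWR      3  418.2197        418      small
```

The 20-mer stays intact under trypsin (K before P is not cleaved) and is
routed as a large fragment (S1 uptake); ALK (331 Da) is small and bypasses
S1.

The end-to-end pipeline (`runPipeline(runConfig(...))`) chains
simulate → preprocess → decompose → kinetics and archives its exact
configuration with a machine-readable summary; identical configurations
reproduce the summary byte for byte.

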