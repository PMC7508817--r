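# Default configuration for floatload.
#
# The trait values below are calibrated synthetic stand-ins for a literature
# synthesis of water-hyacinth traits (the primary sources are not bundled with
# the package). They are chosen so that biomass_per_area * content reproduces
# per-area nutrient densities of 9.67 g P m^-2 and 47.8 g N m^-2 at full
# canopy cover. Override any of them with your own traits CSV via
# synthesize_traits().
#
# Units: biomass_per_area in kg dry weight m^-2; contents as fraction of dry
# weight; rel_se is the standard error of the mean divided by the mean.
year_seconds: 31536000  # 365-day year
traits:
  biomass_per_area:
    mean: 2.0
    rel_se: 0.13
    n_studies: 15
  p_content:
    mean: 0.004836
    rel_se: 0.076
    n_studies: 17
  n_content:
    mean: 0.02391
    rel_se: 0.10
    n_studies: 14
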