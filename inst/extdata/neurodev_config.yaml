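# Configuration of external constants for the neurodevelopmental clock.
# These are documented synthetic values (see hominins_synthetic.csv): the
# prenatal growth rate is back-solved so that the synthetic hominin fixture
# reproduces the published raw gestation extremes; swap in measured constants
# for a real analysis.
growth_rate: 11.5        # prenatal growth rate, g/day
rescale_bounds: [245, 275]  # adjusted gestation interval, days
ecv_to_mass:
  method: identity       # endocranial volume (cc) -> brain mass (g)
  density: 1.0
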