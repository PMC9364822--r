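version: HCSP-2015
protein_cap: 11.0
components:
  energy:
    general:
      thresholds:
      - 335.0
      - 670.0
      - 1005.0
      - 1340.0
      - 1675.0
      - 2010.0
      - 2345.0
      - 2680.0
      - 3015.0
      - 3350.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
    beverage:
      thresholds:
      - 0.0
      - 30.0
      - 60.0
      - 90.0
      - 120.0
      - 150.0
      - 180.0
      - 210.0
      - 240.0
      - 270.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
  sugars:
    general:
      thresholds:
      - 4.5
      - 9.0
      - 13.5
      - 18.0
      - 22.5
      - 27.0
      - 31.0
      - 36.0
      - 40.0
      - 45.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
    beverage:
      thresholds:
      - 0.0
      - 1.5
      - 3.0
      - 4.5
      - 6.0
      - 7.5
      - 9.0
      - 10.5
      - 12.0
      - 13.5
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
  satfat:
    general:
      thresholds:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
    added_fat:
      thresholds:
      - 10.0
      - 16.0
      - 22.0
      - 28.0
      - 34.0
      - 40.0
      - 46.0
      - 52.0
      - 58.0
      - 64.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
  sodium:
    general:
      thresholds:
      - 90.0
      - 180.0
      - 270.0
      - 360.0
      - 450.0
      - 540.0
      - 630.0
      - 720.0
      - 810.0
      - 900.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 7.0
      - 8.0
      - 9.0
      - 10.0
  fiber:
    general:
      thresholds:
      - 0.7
      - 1.4
      - 2.1
      - 2.8
      - 3.5
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
  protein:
    general:
      thresholds:
      - 1.6
      - 3.2
      - 4.8
      - 6.4
      - 8.0
      points:
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
  fvln:
    general:
      thresholds:
      - 40.0
      - 60.0
      - 80.0
      points:
      - 1.0
      - 2.0
      - 5.0
    beverage:
      thresholds:
      - 40.0
      - 60.0
      - 80.0
      points:
      - 2.0
      - 4.0
      - 10.0
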