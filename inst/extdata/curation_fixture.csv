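smiles,score,label,abs_query,em_query,solvent_smiles,property,value
C1CC,,fluorescent,370,440,O,em_wavelength,500
Oc1ccccc1,,fluorescent,370,440,,,
OC1=CC=CC=C1,,fluorescent,370,440,,,
Oc1ccccc1,,non-fluorescent,370,440,,,
c1ccc2ccccc2c1,,,,,O,plqy,1.2
c1ccc2ccccc2c1,,,,,O,abs_wavelength,1600
c1ccc2ccccc2c1,,,,,O,log10_eps,7.5
c1ccc2ccccc2c1,,,,,,em_wavelength,520
c1ccc2ccccc2c1,,,,,gas,em_wavelength,480
Cc1ccccc1,,fluorescent,370,440,CCO,em_wavelength,500
Cc1ccccc1,,,,,CCO,em_wavelength,503
Cc1ccccc1,,,,,CCO,em_wavelength,520
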