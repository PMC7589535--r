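# restrained-mean-position FRET restraints (AMBER DISANG dialect)
# conformer: theta_20
# pseudoatom serials start at 33 in pseudoatom-table order
# regenerate from a fresh snapshot at the MD wrapper's cadence (e.g. every 2 ns); pseudoatoms must be massless-excluded from protein/solvent nonbonded interactions
 &rst iat=33,3, r1=5.0122, r2=10.0122, r3=10.0122, r4=15.0122, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,4, r1=6.4458, r2=11.4458, r3=11.4458, r4=16.4458, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,5, r1=3.1688, r2=8.1688, r3=8.1688, r4=13.1688, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,6, r1=3.8577, r2=8.8577, r3=8.8577, r4=13.8577, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,7, r1=0.3183, r2=5.3183, r3=5.3183, r4=10.3183, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,8, r1=0.0000, r2=3.8442, r3=3.8442, r4=8.8442, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,9, r1=3.6550, r2=8.6550, r3=8.6550, r4=13.6550, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,10, r1=4.4445, r2=9.4445, r3=9.4445, r4=14.4445, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,11, r1=5.3673, r2=10.3673, r3=10.3673, r4=15.3673, rk2=1.799079, rk3=1.799079, /
 &rst iat=33,12, r1=6.7198, r2=11.7198, r3=11.7198, r4=16.7198, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,19, r1=5.5063, r2=10.5063, r3=10.5063, r4=15.5063, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,20, r1=6.9051, r2=11.9051, r3=11.9051, r4=16.9051, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,21, r1=3.7301, r2=8.7301, r3=8.7301, r4=13.7301, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,22, r1=4.4593, r2=9.4593, r3=9.4593, r4=14.4593, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,23, r1=0.6259, r2=5.6259, r3=5.6259, r4=10.6259, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,24, r1=0.0000, r2=4.1259, r3=4.1259, r4=9.1259, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,25, r1=3.7265, r2=8.7265, r3=8.7265, r4=13.7265, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,26, r1=4.4497, r2=9.4497, r3=9.4497, r4=14.4497, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,27, r1=5.5205, r2=10.5205, r3=10.5205, r4=15.5205, rk2=1.799079, rk3=1.799079, /
 &rst iat=34,28, r1=6.9194, r2=11.9194, r3=11.9194, r4=16.9194, rk2=1.799079, rk3=1.799079, /
 &rst iat=35,5, r1=5.4576, r2=10.4576, r3=10.4576, r4=15.4576, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,6, r1=6.8392, r2=11.8392, r3=11.8392, r4=16.8392, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,7, r1=3.7062, r2=8.7062, r3=8.7062, r4=13.7062, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,8, r1=4.4601, r2=9.4601, r3=9.4601, r4=14.4601, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,9, r1=0.5043, r2=5.5043, r3=5.5043, r4=10.5043, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,10, r1=0.0000, r2=4.0081, r3=4.0081, r4=9.0081, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,11, r1=3.5121, r2=8.5121, r3=8.5121, r4=13.5121, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,12, r1=4.2213, r2=9.2213, r3=9.2213, r4=14.2213, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,13, r1=5.3281, r2=10.3281, r3=10.3281, r4=15.3281, rk2=1.439263, rk3=1.439263, /
 &rst iat=35,14, r1=6.7416, r2=11.7416, r3=11.7416, r4=16.7416, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,21, r1=5.3641, r2=10.3641, r3=10.3641, r4=15.3641, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,22, r1=6.7194, r2=11.7194, r3=11.7194, r4=16.7194, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,23, r1=3.6367, r2=8.6367, r3=8.6367, r4=13.6367, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,24, r1=4.4200, r2=9.4200, r3=9.4200, r4=14.4200, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,25, r1=0.3142, r2=5.3142, r3=5.3142, r4=10.3142, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,26, r1=0.0000, r2=3.8376, r3=3.8376, r4=8.8376, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,27, r1=3.1843, r2=8.1843, r3=8.1843, r4=13.1843, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,28, r1=3.8804, r2=8.8804, r3=8.8804, r4=13.8804, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,29, r1=5.0133, r2=10.0133, r3=10.0133, r4=15.0133, rk2=1.439263, rk3=1.439263, /
 &rst iat=36,30, r1=6.4448, r2=11.4448, r3=11.4448, r4=16.4448, rk2=1.439263, rk3=1.439263, /
 &rst iat=33,34, r1=19.0729, r2=23.0729, r3=27.0729, r4=31.0729, rk2=0.089954, rk3=0.089954, /
 &rst iat=35,36, r1=19.5799, r2=24.5799, r3=29.5799, r4=34.5799, rk2=0.071963, rk3=0.071963, /
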