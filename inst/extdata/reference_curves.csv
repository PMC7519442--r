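compound,tissue,slope,intercept,r,range_low,range_high,lloq
psoralen,heart,7.77e-3,2.23e-2,1.0000,1,1000,1.0
psoralen,liver,3.60e-3,1.03e-1,1.0000,5,1000,5.0
psoralen,spleen,5.71e-3,2.92e-2,0.9995,5,1000,5.0
psoralen,lung,2.44e-3,3.33e-2,0.9980,5,1000,5.0
psoralen,kidney,3.44e-3,1.21e-1,0.9996,2,1000,2.0
psoralen,uterus,8.62e-3,8.86e-3,1.0000,1,1000,1.0
psoralen,ovary,6.53e-3,1.79e-2,1.0000,5,1000,5.0
psoralen,testes,5.04e-3,4.89e-2,1.0000,1,1000,1.0
isopsoralen,heart,8.57e-3,3.61e-2,1.0000,1,1000,1.0
isopsoralen,liver,1.65e-3,1.74e-1,0.9986,5,1000,5.0
isopsoralen,spleen,4.55e-3,3.50e-2,0.9981,5,1000,5.0
isopsoralen,lung,1.48e-3,5.62e-2,0.9970,5,1000,5.0
isopsoralen,kidney,2.34e-3,1.77e-1,0.9994,2,1000,2.0
isopsoralen,uterus,6.23e-3,2.86e-2,1.0000,1,500,1.0
isopsoralen,ovary,6.12e-3,5.19e-2,1.0000,5,1000,5.0
isopsoralen,testes,4.27e-3,7.24e-2,0.9997,5,1000,5.0
bavachin,heart,2.31e-2,-6.13e-3,1.0000,0.4,50,0.4
bavachin,liver,3.17e-2,8.99e-2,0.9977,1,500,1.0
bavachin,spleen,2.61e-2,3.94e-2,1.0000,1,200,1.0
bavachin,lung,4.07e-2,2.90e-2,0.9976,0.5,200,0.5
bavachin,kidney,2.19e-2,6.66e-3,0.9999,1,500,1.0
bavachin,uterus,2.11e-2,-4.30e-2,0.9997,1,200,1.0
bavachin,ovary,3.70e-2,-1.14e-2,1.0000,1,50,1.0
bavachin,testes,2.14e-2,-2.71e-2,0.9897,1,50,1.0
isobavachin,heart,4.07e-2,8.55e-3,0.9996,0.3,50,0.3
isobavachin,liver,5.35e-2,5.28e-2,0.9999,1,250,1.0
isobavachin,spleen,3.82e-2,8.21e-2,0.9995,0.5,100,0.5
isobavachin,lung,5.94e-2,3.32e-2,0.9976,0.5,100,0.5
isobavachin,kidney,4.62e-2,1.85e-2,1.0000,0.1,250,0.1
isobavachin,uterus,3.93e-2,3.14e-3,1.0000,0.1,50,0.1
isobavachin,ovary,7.17e-2,-7.18e-2,0.9999,1,50,1.0
isobavachin,testes,3.94e-2,7.50e-2,0.9887,0.5,50,0.5
pinoresinol_diglucoside,heart,6.50e-4,-2.98e-4,1.0000,0.5,100,0.5
pinoresinol_diglucoside,liver,8.57e-4,6.87e-5,0.9999,0.5,250,0.5
pinoresinol_diglucoside,spleen,4.46e-4,5.35e-4,1.0000,0.5,100,0.5
pinoresinol_diglucoside,lung,6.95e-4,1.26e-3,1.0000,0.5,500,0.5
pinoresinol_diglucoside,kidney,3.45e-4,5.16e-4,0.9998,1,1000,1.0
pinoresinol_diglucoside,uterus,6.24e-4,6.35e-4,0.9996,0.5,100,0.5
pinoresinol_diglucoside,ovary,7.81e-4,-3.66e-4,0.9997,0.5,100,0.5
pinoresinol_diglucoside,testes,6.90e-4,6.48e-4,0.9999,0.5,50,0.5
psoralenoside,heart,6.99e-4,2.09e-3,0.9993,5,1000,5.0
psoralenoside,liver,4.63e-4,1.21e-2,0.9996,5,1000,5.0
psoralenoside,spleen,5.56e-4,2.73e-3,0.9975,5,1000,5.0
psoralenoside,lung,9.26e-4,2.96e-2,0.9998,1,1000,1.0
psoralenoside,kidney,3.61e-4,8.94e-3,0.9991,5,2000,5.0
psoralenoside,uterus,9.86e-4,3.82e-2,0.9994,5,2000,5.0
psoralenoside,ovary,6.00e-4,1.93e-2,0.9998,5,2000,5.0
psoralenoside,testes,5.16e-4,1.57e-2,0.9973,5,1000,5.0
isobavachalcone,heart,4.89e-2,-5.05e-2,0.9997,1,50,1.0
isobavachalcone,liver,8.17e-2,9.05e-2,0.9973,1,100,1.0
isobavachalcone,spleen,4.86e-2,6.15e-2,0.9998,0.5,250,0.5
isobavachalcone,lung,4.93e-2,1.59e-3,0.9998,0.5,250,0.5
isobavachalcone,kidney,3.18e-2,2.75e-2,0.9993,1,500,1.0
isobavachalcone,uterus,3.47e-2,-4.89e-2,0.9995,1,50,1.0
isobavachalcone,ovary,2.29e-2,1.08e-2,0.9999,0.5,50,0.5
isobavachalcone,testes,2.88e-2,2.11e-2,1.0000,0.5,50,0.5
bavachalcone,heart,2.47e-2,-8.09e-3,0.9967,0.3,25,0.3
bavachalcone,liver,2.83e-2,1.88e-2,0.9999,0.5,250,0.5
bavachalcone,spleen,2.83e-2,2.61e-2,0.9996,0.5,50,0.5
bavachalcone,lung,3.05e-2,3.49e-2,0.9997,0.5,100,0.5
bavachalcone,kidney,3.01e-2,2.78e-2,0.9992,0.5,100,0.5
bavachalcone,uterus,3.25e-2,-2.93e-2,0.9998,0.5,250,0.5
bavachalcone,ovary,2.17e-2,1.12e-2,1.0000,0.5,50,0.5
bavachalcone,testes,2.63e-2,-1.85e-2,0.9996,0.5,50,0.5
geniposidic_acid,heart,1.11e-3,4.13e-4,0.9996,1,500,1.0
geniposidic_acid,liver,6.88e-4,3.58e-3,0.9993,1,1000,1.0
geniposidic_acid,spleen,1.31e-3,1.03e-3,0.9990,1,500,1.0
geniposidic_acid,lung,8.89e-4,1.78e-3,0.9986,1,1000,1.0
geniposidic_acid,kidney,8.11e-4,-1.72e-3,0.9992,1,2000,1.0
geniposidic_acid,uterus,5.08e-3,1.48e-2,0.9995,0.5,500,0.5
geniposidic_acid,ovary,8.04e-4,7.50e-4,0.9990,1,1000,1.0
geniposidic_acid,testes,5.83e-4,3.28e-4,0.9956,1,250,1.0
psoralidin,heart,9.87e-3,-2.03e-3,0.9999,1,250,1.0
psoralidin,liver,7.80e-3,1.11e-2,0.9997,1,500,1.0
psoralidin,spleen,2.43e-2,-2.60e-3,0.9998,1,500,1.0
psoralidin,lung,1.54e-2,1.70e-2,0.9993,1,500,1.0
psoralidin,kidney,6.92e-2,3.91e-3,0.9996,1,1000,1.0
psoralidin,uterus,3.96e-2,-6.48e-2,0.9996,1,250,1.0
psoralidin,ovary,2.11e-2,1.84e-2,0.9999,0.5,100,0.5
psoralidin,testes,1.56e-2,1.59e-2,0.9996,0.5,50,0.5
neobavaisoflavone,heart,1.39e-2,-5.15e-3,0.9994,0.5,50,0.5
neobavaisoflavone,liver,7.88e-3,5.31e-2,0.9991,1,1000,1.0
neobavaisoflavone,spleen,2.06e-2,4.61e-2,0.9998,1,500,1.0
neobavaisoflavone,lung,1.43e-2,3.16e-2,1.0000,1,300,1.0
neobavaisoflavone,kidney,1.26e-2,-4.05e-3,0.9994,1,1000,1.0
neobavaisoflavone,uterus,6.00e-2,-1.22e-1,0.9997,1,50,1.0
neobavaisoflavone,ovary,1.81e-2,1.16e-2,0.9996,1,100,1.0
neobavaisoflavone,testes,1.40e-2,1.36e-2,0.9998,1,50,1.0
bavachinin,heart,2.72e-3,-2.72e-3,0.9999,1,100,1.0
bavachinin,liver,1.48e-3,3.93e-3,0.9998,1,1000,1.0
bavachinin,spleen,7.85e-3,-2.00e-2,0.9995,1,1000,1.0
bavachinin,lung,4.39e-3,-7.75e-4,0.9994,1,500,1.0
bavachinin,kidney,3.51e-3,-3.14e-3,0.9992,1,500,1.0
bavachinin,uterus,1.21e-2,-1.96e-2,0.9997,1,50,1.0
bavachinin,ovary,6.56e-3,-9.65e-4,0.9997,1,50,1.0
bavachinin,testes,2.72e-3,-2.72e-3,0.9999,1,100,1.0
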