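class_name,discovery_year,clinical_use_year,resistance_year
synthetic_sulfonamide,1935,1936,1942
synthetic_beta_lactam,1940,1943,1947
synthetic_aminoglycoside,1944,1946,1950
synthetic_tetracycline,1948,1952,1959
synthetic_macrolide,1952,1955,1968
synthetic_glycopeptide,1957,1958,1988
synthetic_quinolone,1962,1967,1998
synthetic_oxazolidinone,1987,2000,
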