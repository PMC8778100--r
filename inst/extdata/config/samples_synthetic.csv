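region,flowering_date,observed_harvest_date,observed_yield,plant_density,tree_age
Apartado,2019-07-12,2020-01-08,3378,1100,8
Apartado,2019-07-28,2020-01-24,3378,1100,8
Apartado,2019-08-13,2020-02-09,3378,1100,8
Apartado,2019-08-28,2020-02-24,3378,1100,8
Apartado,2019-09-13,2020-03-11,3378,1100,8
Apartado,2019-09-29,2020-03-27,3378,1100,8
Apartado,2019-10-15,2020-04-12,3378,1100,8
Apartado,2019-10-30,2020-04-27,3378,1100,8
Apartado,2019-11-15,2020-05-13,3378,1100,8
Apartado,2019-12-01,2020-05-29,3378,1100,8
Apartado,2019-12-17,2020-06-14,3378,1100,8
Apartado,2020-01-02,2020-06-30,3378,1100,8
Apartado,2020-01-17,2020-07-15,3378,1100,8
Apartado,2020-02-02,2020-07-31,3378,1100,8
Apartado,2020-02-18,2020-08-16,3378,1100,8
Apartado,2020-03-05,2020-09-01,3378,1100,8
Apartado,2020-03-20,2020-09-16,3378,1100,8
Apartado,2020-04-05,2020-10-02,3378,1100,8
Apartado,2020-04-21,2020-10-18,3378,1100,8
Apartado,2020-05-07,2020-11-03,3378,1100,8
Apartado,2020-05-22,2020-11-18,3378,1100,8
Apartado,2020-06-07,2020-12-04,3378,1100,8
Apartado,2020-06-23,2020-12-20,3378,1100,8
Arauca,2019-07-12,2020-01-08,3981,1100,8
Arauca,2019-07-28,2020-01-24,3981,1100,8
Arauca,2019-08-13,2020-02-09,3981,1100,8
Arauca,2019-08-28,2020-02-24,3981,1100,8
Arauca,2019-09-13,2020-03-11,3981,1100,8
Arauca,2019-09-29,2020-03-27,3981,1100,8
Arauca,2019-10-15,2020-04-12,3981,1100,8
Arauca,2019-10-30,2020-04-27,3981,1100,8
Arauca,2019-11-15,2020-05-13,3981,1100,8
Arauca,2019-12-01,2020-05-29,3981,1100,8
Arauca,2019-12-17,2020-06-14,3981,1100,8
Arauca,2020-01-02,2020-06-30,3981,1100,8
Arauca,2020-01-17,2020-07-15,3981,1100,8
Arauca,2020-02-02,2020-07-31,3981,1100,8
Arauca,2020-02-18,2020-08-16,3981,1100,8
Arauca,2020-03-05,2020-09-01,3981,1100,8
Arauca,2020-03-20,2020-09-16,3981,1100,8
Arauca,2020-04-05,2020-10-02,3981,1100,8
Arauca,2020-04-21,2020-10-18,3981,1100,8
Arauca,2020-05-07,2020-11-03,3981,1100,8
Arauca,2020-05-22,2020-11-18,3981,1100,8
Arauca,2020-06-07,2020-12-04,3981,1100,8
Arauca,2020-06-23,2020-12-20,3981,1100,8
Santander,2019-07-12,2020-01-08,2687,1100,8
Santander,2019-07-28,2020-01-24,2687,1100,8
Santander,2019-08-13,2020-02-09,2687,1100,8
Santander,2019-08-28,2020-02-24,2687,1100,8
Santander,2019-09-13,2020-03-11,2687,1100,8
Santander,2019-09-29,2020-03-27,2687,1100,8
Santander,2019-10-15,2020-04-12,2687,1100,8
Santander,2019-10-30,2020-04-27,2687,1100,8
Santander,2019-11-15,2020-05-13,2687,1100,8
Santander,2019-12-01,2020-05-29,2687,1100,8
Santander,2019-12-17,2020-06-14,2687,1100,8
Santander,2020-01-02,2020-06-30,2687,1100,8
Santander,2020-01-17,2020-07-15,2687,1100,8
Santander,2020-02-02,2020-07-31,2687,1100,8
Santander,2020-02-18,2020-08-16,2687,1100,8
Santander,2020-03-05,2020-09-01,2687,1100,8
Santander,2020-03-20,2020-09-16,2687,1100,8
Santander,2020-04-05,2020-10-02,2687,1100,8
Santander,2020-04-21,2020-10-18,2687,1100,8
Santander,2020-05-07,2020-11-03,2687,1100,8
Santander,2020-05-22,2020-11-18,2687,1100,8
Santander,2020-06-07,2020-12-04,2687,1100,8
Santander,2020-06-23,2020-12-20,2687,1100,8
Cali,2019-07-12,2020-01-08,1900,1100,8
Cali,2019-07-28,2020-01-24,1900,1100,8
Cali,2019-08-13,2020-02-09,1900,1100,8
Cali,2019-08-28,2020-02-24,1900,1100,8
Cali,2019-09-13,2020-03-11,1900,1100,8
Cali,2019-09-29,2020-03-27,1900,1100,8
Cali,2019-10-15,2020-04-12,1900,1100,8
Cali,2019-10-30,2020-04-27,1900,1100,8
Cali,2019-11-15,2020-05-13,1900,1100,8
Cali,2019-12-01,2020-05-29,1900,1100,8
Cali,2019-12-17,2020-06-14,1900,1100,8
Cali,2020-01-02,2020-06-30,1900,1100,8
Cali,2020-01-17,2020-07-15,1900,1100,8
Cali,2020-02-02,2020-07-31,1900,1100,8
Cali,2020-02-18,2020-08-16,1900,1100,8
Cali,2020-03-05,2020-09-01,1900,1100,8
Cali,2020-03-20,2020-09-16,1900,1100,8
Cali,2020-04-05,2020-10-02,1900,1100,8
Cali,2020-04-21,2020-10-18,1900,1100,8
Cali,2020-05-07,2020-11-03,1900,1100,8
Cali,2020-05-22,2020-11-18,1900,1100,8
Cali,2020-06-07,2020-12-04,1900,1100,8
Cali,2020-06-23,2020-12-20,1900,1100,8
Caldas,2019-07-12,2020-01-08,740,1100,8
Caldas,2019-07-28,2020-01-24,740,1100,8
Caldas,2019-08-13,2020-02-09,740,1100,8
Caldas,2019-08-28,2020-02-24,740,1100,8
Caldas,2019-09-13,2020-03-11,740,1100,8
Caldas,2019-09-29,2020-03-27,740,1100,8
Caldas,2019-10-15,2020-04-12,740,1100,8
Caldas,2019-10-30,2020-04-27,740,1100,8
Caldas,2019-11-15,2020-05-13,740,1100,8
Caldas,2019-12-01,2020-05-29,740,1100,8
Caldas,2019-12-17,2020-06-14,740,1100,8
Caldas,2020-01-02,2020-06-30,740,1100,8
Caldas,2020-01-17,2020-07-15,740,1100,8
Caldas,2020-02-02,2020-07-31,740,1100,8
Caldas,2020-02-18,2020-08-16,740,1100,8
Caldas,2020-03-05,2020-09-01,740,1100,8
Caldas,2020-03-20,2020-09-16,740,1100,8
Caldas,2020-04-05,2020-10-02,740,1100,8
Caldas,2020-04-21,2020-10-18,740,1100,8
Caldas,2020-05-07,2020-11-03,740,1100,8
Caldas,2020-05-22,2020-11-18,740,1100,8
Caldas,2020-06-07,2020-12-04,740,1100,8
Caldas,2020-06-23,2020-12-20,740,1100,8
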