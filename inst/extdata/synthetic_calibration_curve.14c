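# synthetic_calibration_curve.14c
# SYNTHETIC calibration curve for examples and tests only: a smooth
# wiggle-added stand-in in the IntCal text layout (CAL BP, 14C age,
# Error). Not a measured atmospheric curve.
4000,3657.5,11.7
4005,3668.0,11.7
4010,3678.4,11.7
4015,3688.1,11.8
4020,3696.3,11.8
4025,3702.8,11.8
4030,3707.5,11.9
4035,3710.6,11.9
4040,3712.8,11.9
4045,3714.8,11.9
4050,3717.3,11.9
4055,3721.2,12.0
4060,3727.1,12.0
4065,3735.2,12.0
4070,3745.6,12.0
4075,3758.1,12.0
4080,3772.1,12.0
4085,3786.8,12.0
4090,3801.3,12.0
4095,3814.9,12.0
4100,3826.6,12.0
4105,3836.2,12.0
4110,3843.5,12.0
4115,3848.6,12.0
4120,3851.9,11.9
4125,3854.1,11.9
4130,3856.1,11.9
4135,3858.5,11.9
4140,3862.2,11.8
4145,3867.5,11.8
4150,3874.7,11.8
4155,3883.5,11.8
4160,3893.5,11.7
4165,3904.1,11.7
4170,3914.4,11.6
4175,3923.6,11.6
4180,3930.9,11.5
4185,3936.0,11.5
4190,3938.5,11.5
4195,3938.6,11.4
4200,3936.6,11.3
4205,3933.3,11.3
4210,3929.5,11.2
4215,3925.9,11.2
4220,3923.6,11.1
4225,3922.9,11.0
4230,3924.2,11.0
4235,3927.7,10.9
4240,3932.8,10.8
4245,3939.1,10.8
4250,3945.9,10.7
4255,3952.3,10.6
4260,3957.6,10.5
4265,3961.3,10.5
4270,3963.0,10.4
4275,3962.7,10.3
4280,3960.9,10.2
4285,3958.0,10.1
4290,3954.9,10.1
4295,3952.4,10.0
4300,3951.3,9.9
4305,3952.3,9.8
4310,3955.8,9.7
4315,3961.9,9.6
4320,3970.3,9.5
4325,3980.6,9.4
4330,3991.9,9.3
4335,4003.4,9.2
4340,4014.4,9.1
4345,4024.1,9.1
4350,4032.1,9.0
4355,4038.3,8.9
4360,4042.7,8.8
4365,4045.9,8.7
4370,4048.5,8.6
4375,4051.4,8.5
4380,4055.3,8.4
4385,4060.8,8.3
4390,4068.5,8.2
4395,4078.4,8.1
4400,4090.3,8.0
4405,4103.9,8.1
4410,4118.4,8.2
4415,4132.9,8.3
4420,4146.6,8.4
4425,4158.7,8.5
4430,4168.7,8.6
4435,4176.2,8.7
4440,4181.4,8.8
4445,4184.5,8.9
4450,4186.3,9.0
4455,4187.4,9.1
4460,4188.8,9.2
4465,4191.1,9.3
4470,4194.8,9.4
4475,4200.4,9.5
4480,4207.6,9.6
4485,4216.3,9.7
4490,4225.8,9.8
4495,4235.3,9.9
4500,4244.0,9.9
4505,4251.1,10.0
4510,4256.1,10.1
4515,4258.7,10.2
4520,4258.8,10.3
4525,4256.7,10.4
4530,4253.2,10.4
4535,4248.9,10.5
4540,4244.7,10.6
4545,4241.5,10.7
4550,4239.9,10.8
4555,4240.3,10.8
4560,4243.0,10.9
4565,4247.6,11.0
4570,4253.7,11.0
4575,4260.6,11.1
4580,4267.6,11.2
4585,4273.7,11.2
4590,4278.5,11.3
4595,4281.5,11.3
4600,4282.5,11.4
4605,4281.9,11.4
4610,4280.1,11.5
4615,4277.8,11.5
4620,4275.9,11.6
4625,4275.2,11.6
4630,4276.4,11.7
4635,4280.0,11.7
4640,4286.2,11.7
4645,4294.9,11.8
4650,4305.6,11.8
4655,4317.6,11.8
4660,4330.1,11.9
4665,4342.2,11.9
4670,4353.3,11.9
4675,4362.7,11.9
4680,4370.2,11.9
4685,4375.9,12.0
4690,4380.1,12.0
4695,4383.3,12.0
4700,4386.4,12.0
4705,4390.2,12.0
4710,4395.3,12.0
4715,4402.3,12.0
4720,4411.4,12.0
4725,4422.7,12.0
4730,4435.6,12.0
4735,4449.6,12.0
4740,4463.8,12.0
4745,4477.4,11.9
4750,4489.6,11.9
4755,4499.7,11.9
4760,4507.4,11.9
4765,4512.6,11.9
4770,4515.5,11.8
4775,4516.8,11.8
4780,4517.2,11.8
4785,4517.4,11.7
4790,4518.3,11.7
4795,4520.5,11.7
4800,4524.4,11.6
4805,4530.1,11.6
4810,4537.4,11.5
4815,4545.7,11.5
4820,4554.3,11.4
4825,4562.5,11.4
4830,4569.5,11.3
4835,4574.5,11.3
4840,4577.2,11.2
4845,4577.5,11.2
4850,4575.7,11.1
4855,4572.1,11.0
4860,4567.6,11.0
4865,4563.0,10.9
4870,4559.2,10.8
4875,4556.9,10.7
4880,4556.6,10.7
4885,4558.7,10.6
4890,4562.9,10.5
4895,4568.9,10.4
4900,4576.0,10.4
4905,4583.6,10.3
4910,4590.7,10.2
4915,4596.7,10.1
4920,4601.0,10.0
4925,4603.6,9.9
4930,4604.3,9.9
4935,4603.8,9.8
4940,4602.5,9.7
4945,4601.3,9.6
4950,4601.1,9.5
4955,4602.6,9.4
4960,4606.3,9.3
4965,4612.6,9.2
4970,4621.5,9.1
4975,4632.4,9.0
4980,4645.0,8.9
4985,4658.2,8.8
4990,4671.4,8.7
4995,4683.7,8.6
5000,4694.4,8.5
5005,4703.1,8.4
5010,4709.9,8.3
5015,4714.9,8.2
5020,4718.7,8.1
5025,4721.9,8.0
5030,4725.5,8.1
5035,4730.1,8.2
5040,4736.3,8.3
5045,4744.5,8.4
5050,4754.7,8.5
5055,4766.8,8.6
5060,4780.0,8.7
5065,4793.7,8.8
5070,4807.0,8.9
5075,4819.0,9.0
5080,4829.1,9.1
5085,4836.8,9.2
5090,4841.9,9.2
5095,4844.7,9.3
5100,4845.5,9.4
5105,4845.1,9.5
5110,4844.3,9.6
5115,4843.9,9.7
5120,4844.6,9.8
5125,4846.9,9.9
5130,4851.0,10.0
5135,4856.9,10.1
5140,4864.0,10.1
5145,4871.8,10.2
5150,4879.5,10.3
5155,4886.3,10.4
5160,4891.5,10.5
5165,4894.5,10.6
5170,4895.2,10.6
5175,4893.7,10.7
5180,4890.4,10.8
5185,4885.9,10.8
5190,4881.2,10.9
5195,4877.1,11.0
5200,4874.4,11.1
5205,4873.6,11.1
5210,4875.2,11.2
5215,4879.1,11.2
5220,4885.1,11.3
5225,4892.6,11.3
5230,4900.7,11.4
5235,4908.8,11.5
5240,4916.1,11.5
5245,4921.9,11.6
5250,4926.0,11.6
5255,4928.3,11.6
5260,4929.1,11.7
5265,4929.0,11.7
5270,4928.7,11.8
5275,4929.1,11.8
5280,4930.9,11.8
5285,4934.8,11.8
5290,4941.1,11.9
5295,4950.0,11.9
5300,4961.1,11.9
5305,4973.9,11.9
5310,4987.8,12.0
5315,5001.7,12.0
5320,5014.9,12.0
5325,5026.7,12.0
5330,5036.5,12.0
5335,5044.2,12.0
5340,5050.0,12.0
5345,5054.2,12.0
5350,5057.5,12.0
5355,5060.8,12.0
5360,5064.7,12.0
5365,5070.0,12.0
5370,5077.1,12.0
5375,5086.2,11.9
5380,5097.1,11.9
5385,5109.3,11.9
5390,5122.2,11.9
5395,5135.0,11.9
5400,5146.7,11.8
5405,5156.6,11.8
5410,5164.2,11.8
5415,5169.3,11.7
5420,5171.8,11.7
5425,5172.2,11.6
5430,5171.2,11.6
5435,5169.4,11.6
5440,5167.8,11.5
5445,5167.1,11.5
5450,5167.9,11.4
5455,5170.5,11.4
5460,5175.0,11.3
5465,5181.1,11.3
5470,5188.1,11.2
5475,5195.3,11.1
5480,5202.0,11.1
5485,5207.3,11.0
5490,5210.8,10.9
5495,5212.1,10.9
5500,5211.2,10.8
5505,5208.4,10.7
5510,5204.3,10.7
5515,5199.8,10.6
5520,5195.6,10.5
5525,5192.7,10.4
5530,5191.7,10.3
5535,5193.0,10.3
5540,5196.7,10.2
5545,5202.7,10.1
5550,5210.5,10.0
5555,5219.3,9.9
5560,5228.4,9.8
5565,5237.0,9.7
5570,5244.3,9.6
5575,5250.0,9.6
5580,5253.9,9.5
5585,5256.2,9.4
5590,5257.3,9.3
5595,5258.0,9.2
5600,5259.0,9.1
5605,5261.1,9.0
5610,5265.1,8.9
5615,5271.4,8.8
5620,5280.2,8.7
5625,5291.3,8.6
5630,5304.2,8.5
5635,5318.3,8.4
5640,5332.8,8.3
5645,5346.7,8.2
5650,5359.3,8.1
5655,5370.0,8.0
5660,5378.5,8.1
5665,5384.9,8.2
5670,5389.5,8.3
5675,5392.8,8.4
5680,5395.7,8.5
5685,5398.9,8.6
5690,5403.1,8.7
5695,5409.0,8.8
5700,5416.7,8.9
5705,5426.3,9.0
5710,5437.3,9.1
5715,5449.2,9.2
5720,5461.2,9.3
5725,5472.4,9.4
5730,5482.1,9.5
5735,5489.6,9.6
5740,5494.5,9.7
5745,5496.9,9.7
5750,5497.0,9.8
5755,5495.4,9.9
5760,5492.8,10.0
5765,5490.1,10.1
5770,5488.2,10.2
5775,5487.6,10.3
5780,5488.9,10.3
5785,5492.1,10.4
5790,5497.1,10.5
5795,5503.3,10.6
5800,5510.2,10.7
5805,5516.8,10.7
5810,5522.5,10.8
5815,5526.5,10.9
5820,5528.6,10.9
5825,5528.5,11.0
5830,5526.5,11.1
5835,5523.1,11.1
5840,5519.0,11.2
5845,5515.1,11.3
5850,5512.2,11.3
5855,5511.0,11.4
5860,5512.2,11.4
5865,5515.9,11.5
5870,5522.0,11.5
5875,5530.2,11.6
5880,5539.7,11.6
5885,5549.7,11.7
5890,5559.5,11.7
5895,5568.3,11.7
5900,5575.6,11.8
5905,5581.1,11.8
5910,5584.9,11.8
5915,5587.3,11.9
5920,5589.0,11.9
5925,5590.6,11.9
5930,5593.1,11.9
5935,5597.1,11.9
5940,5603.3,12.0
5945,5611.8,12.0
5950,5622.7,12.0
5955,5635.5,12.0
5960,5649.7,12.0
5965,5664.4,12.0
5970,5678.7,12.0
5975,5691.9,12.0
5980,5703.3,12.0
5985,5712.4,12.0
5990,5719.3,12.0
5995,5724.1,12.0
6000,5727.3,12.0
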