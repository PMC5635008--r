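satellite	species	chromosome	pattern	regions
ApaSat01-51	paranae	A	c
ApaSat01-51	fasciatus	A	c
ApaSat01-51	bockmanni	A	c
ApaSat02-236	paranae	A	c
ApaSat02-236	fasciatus	A	c
ApaSat02-236	bockmanni	A	c
ApaSat03-91	paranae	A	c
ApaSat03-91	fasciatus	A	c
ApaSat03-91	bockmanni	A	c
ApaSat04-233	paranae	A	c
ApaSat04-233	fasciatus	A	c
ApaSat04-233	bockmanni	A	c
ApaSat05-23	paranae	A	c
ApaSat05-23	fasciatus	A	ns
ApaSat05-23	bockmanni	A	c
ApaSat06-86	paranae	A	c
ApaSat06-86	fasciatus	A	c
ApaSat06-86	bockmanni	A	c
ApaSat07-6-tel	paranae	A	t
ApaSat07-6-tel	fasciatus	A	t
ApaSat07-6-tel	bockmanni	A	t
ApaSat08-35	paranae	A	c
ApaSat08-35	fasciatus	A	c
ApaSat08-35	bockmanni	A	ns
ApaSat13-22	paranae	A	c
ApaSat13-22	fasciatus	A	c
ApaSat13-22	bockmanni	A	c
ApaSat14-184	paranae	A	c
ApaSat14-184	fasciatus	A	c
ApaSat14-184	bockmanni	A	c
ApaSat15-51	paranae	A	c
ApaSat15-51	fasciatus	A	c
ApaSat15-51	bockmanni	A	c
ApaSat17-365	paranae	A	c
ApaSat17-365	fasciatus	A	c
ApaSat17-365	bockmanni	A	c
ApaSat18-58	paranae	A	c
ApaSat18-58	fasciatus	A	c
ApaSat18-58	bockmanni	A	c
ApaSat19-77	paranae	A	c
ApaSat19-77	fasciatus	A	c
ApaSat19-77	bockmanni	A	c
ApaSat20-18	paranae	A	nc
ApaSat20-18	fasciatus	A	c
ApaSat20-18	bockmanni	A	c
ApaSat22-63	paranae	A	c
ApaSat22-63	fasciatus	A	ns
ApaSat22-63	bockmanni	A	ns
ApaSat23-37	paranae	A	c
ApaSat23-37	fasciatus	A	c
ApaSat23-37	bockmanni	A	c
ApaSat24-78	paranae	A	c
ApaSat24-78	fasciatus	A	c
ApaSat24-78	bockmanni	A	c
ApaSat26-195	paranae	A	c
ApaSat26-195	fasciatus	A	ns
ApaSat26-195	bockmanni	A	c
ApaSat27-178	paranae	A	c
ApaSat27-178	fasciatus	A	ns
ApaSat27-178	bockmanni	A	c
ApaSat28-52	paranae	A	c
ApaSat28-52	fasciatus	A	c
ApaSat28-52	bockmanni	A	c
ApaSat30-50	paranae	A	c
ApaSat30-50	fasciatus	A	c
ApaSat30-50	bockmanni	A	c
ApaSat31-165	paranae	A	c
ApaSat31-165	fasciatus	A	ns
ApaSat31-165	bockmanni	A	c
ApaSat32-85	paranae	A	c
ApaSat32-85	fasciatus	A	ns
ApaSat32-85	bockmanni	A	c
ApaSat33-112	paranae	A	c
ApaSat33-112	fasciatus	A	c
ApaSat33-112	bockmanni	A	c
ApaSat34-59	paranae	A	c
ApaSat34-59	fasciatus	A	c
ApaSat34-59	bockmanni	A	ns
ApaSat35-37	paranae	A	c
ApaSat35-37	fasciatus	A	ns
ApaSat35-37	bockmanni	A	ns
ApaSat36-21	paranae	A	nc
ApaSat36-21	fasciatus	A	ns
ApaSat36-21	bockmanni	A	c
ApaSat37-38	paranae	A	nc
ApaSat37-38	fasciatus	A	ns
ApaSat37-38	bockmanni	A	ns
ApaSat38-107	paranae	A	nc
ApaSat38-107	fasciatus	A	ns
ApaSat38-107	bockmanni	A	ns
ApaSat39-32	paranae	A	c
ApaSat39-32	fasciatus	A	ns
ApaSat39-32	bockmanni	A	c
ApaSat40-189	paranae	A	c
ApaSat40-189	fasciatus	A	ns
ApaSat40-189	bockmanni	A	ns
ApaSat42-90	paranae	A	c
ApaSat42-90	fasciatus	A	ns
ApaSat42-90	bockmanni	A	ns
ApaSat43-61	paranae	A	c
ApaSat43-61	fasciatus	A	c
ApaSat43-61	bockmanni	A	c
ApaSat44-21	paranae	A	nc
ApaSat44-21	fasciatus	A	ns
ApaSat44-21	bockmanni	A	ns
ApaSat45-113	paranae	A	c
ApaSat45-113	fasciatus	A	ns
ApaSat45-113	bockmanni	A	c
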